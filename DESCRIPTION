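Package: audissim
Title: Acoustic Features and Perceptual Dissimilarity of Natural Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how the acoustic structure of short natural
    sounds (vowels from different speakers, musical instrument notes, and
    everyday environmental sounds) relates to their perceived dissimilarity.
    Provides a synthetic 36-item stimulus set with controlled category
    contrasts, onset-based preprocessing (trim, ramp, RMS normalization), an
    acoustic descriptor suite (ERB/gammatone cochleagram, spectral centroid
    and flatness, spectral variability, YIN fundamental frequency and
    aperiodicity, log-attack-time, temporal centroid, and the modulation
    power spectrum), simulated dissimilarity raters and identifiers with
    known ground truth, representational similarity analysis with standard
    and semi-partial Kendall tau and permutation inference, ordinal
    multidimensional scaling by stress majorization, and identification-side
    analyses (accuracy versus chance, subcategory recoding,
    confusion-dissimilarity comparison, split-half reliability).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
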