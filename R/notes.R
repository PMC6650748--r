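#' Equal-tempered note utilities
#'
#' Twelve-tone equal temperament referenced to A4 = 440 Hz. Note names are a
#' pitch class (`C`, `C#`/`Db`, ..., `B`; Unicode flat `♭` is also
#' accepted) followed by an octave number, e.g. `"E3"`, `"Bb2"`, `"A4"`.
#'
#' @name notes
NULL

.PITCH_CLASS <- c(C = 0, `C#` = 1, Db = 1, D = 2, `D#` = 3, Eb = 3, E = 4,
                  `F` = 5, `F#` = 6, Gb = 6, G = 7, `G#` = 8, Ab = 8,
                  A = 9, `A#` = 10, Bb = 10, B = 11)

# MIDI numbers covering A0 (21) .. C8 (108)
.NOTE_RANGE_MIDI <- 21:108

.note_to_midi <- function(note_name) {
  nm <- gsub("♭", "b", trimws(note_name))
  m <- regmatches(nm, regexec("^([A-Ga-g][#b]?)(-?[0-9]+)$", nm))[[1]]
  if (length(m) != 3L) {
    stop("unknown note name: '", note_name, "'", call. = FALSE)
  }
  pc <- m[2]
  substr(pc, 1, 1) <- toupper(substr(pc, 1, 1))
  if (!pc %in% names(.PITCH_CLASS)) {
    stop("unknown note name: '", note_name, "'", call. = FALSE)
  }
  octave <- as.integer(m[3])
  midi <- 12L * (octave + 1L) + as.integer(.PITCH_CLASS[[pc]])
  if (midi < min(.NOTE_RANGE_MIDI) || midi > max(.NOTE_RANGE_MIDI)) {
    stop("note '", note_name, "' outside supported range A0-C8", call. = FALSE)
  }
  midi
}

.midi_to_note <- function(midi) {
  flats <- c("C", "Db", "D", "Eb", "E", "F", "Gb", "G", "Ab", "A", "Bb", "B")
  paste0(flats[(midi %% 12L) + 1L], midi %/% 12L - 1L)
}

#' Convert an equal-tempered note name to frequency
#'
#' @param note_name Pitch class plus octave, within A0--C8 (flats preferred,
#'   sharps accepted).
#' @return Frequency in Hz, referenced to A4 = 440 Hz.
#' @examples
#' note_to_frequency("A4")  # 440
#' note_to_frequency("E3")  # 164.81...
#' @export
note_to_frequency <- function(note_name) {
  midi <- vapply(note_name, .note_to_midi, integer(1))
  unname(440 * 2^((midi - 69) / 12))
}

#' Find the nearest equal-tempered note for a fundamental frequency
#'
#' Returns the note (within A0--C8) whose frequency minimizes the absolute
#' difference in Hz from `f0`; ties are broken toward the lower note.
#'
#' @param f0 Fundamental frequency in Hz (> 0).
#' @return A note name such as `"G2"`.
#' @export
nearest_equal_tempered_note <- function(f0) {
  stopifnot(is.numeric(f0))
  if (any(!is.finite(f0)) || any(f0 <= 0)) {
    stop("f0 must be positive and finite", call. = FALSE)
  }
  freqs <- 440 * 2^((.NOTE_RANGE_MIDI - 69) / 12)
  vapply(f0, function(f) {
    d <- abs(f - freqs)
    # which.min returns the first (lowest-note) index on exact ties
    .midi_to_note(.NOTE_RANGE_MIDI[which.min(d)])
  }, character(1))
}
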