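# Minimal RIFF/WAVE I/O (PCM 16-bit and IEEE float 32-bit).
# Stereo files are reduced to the left channel on read; writing is mono.

#' Write an audio clip to a WAV file
#'
#' @param clip An [audio_clip].
#' @param path Output file path.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  sr <- as.integer(round(clip$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    audio_fmt <- 1L; bits <- 16L
    data <- as.integer(round(pmax(pmin(x, 1), -1) * 32767))
  } else {
    audio_fmt <- 3L; bits <- 32L
    data <- x
  }
  block_align <- bits %/% 8L
  data_bytes <- length(x) * block_align
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # channels
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(data, con, size = 2, endian = "little")
  } else {
    writeBin(data, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into an audio clip
#'
#' Supports linear PCM (16-bit) and IEEE float (32-bit) mono or stereo;
#' stereo is converted to mono by retaining the left channel.
#'
#' @param path WAV file path.
#' @inheritParams audio_clip
#' @return An [audio_clip].
#' @export
read_wav <- function(path, label = basename(path), category = "environmental",
                     subcategory = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_fmt = readBin(con, integer(), size = 2, endian = "little"),
        channels  = readBin(con, integer(), size = 2, endian = "little"),
        sr        = readBin(con, integer(), size = 4, endian = "little"),
        byte_rate = readBin(con, integer(), size = 4, endian = "little"),
        block     = readBin(con, integer(), size = 2, endian = "little"),
        bits      = readBin(con, integer(), size = 2, endian = "little"))
      if (sz > 16L) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = sz)
      if (sz %% 2L == 1L) readBin(con, raw(), n = 1L)
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV", call. = FALSE)
  if (fmt$audio_fmt == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, integer(), n = length(data_raw) %/% 2L,
                 size = 2, signed = TRUE, endian = "little") / 32767
  } else if (fmt$audio_fmt == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, numeric(), n = length(data_raw) %/% 4L,
                 size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32)", call. = FALSE)
  }
  if (fmt$channels > 1L) {
    x <- x[seq(1L, length(x), by = fmt$channels)]  # left channel only
  }
  audio_clip(pmax(pmin(x, 1), -1), fmt$sr, label = label,
             category = category, subcategory = subcategory)
}
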