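# Minimal WAV reader/writer (mono), supporting PCM 16/24-bit and IEEE float
# 32/64-bit. Covers the audio interchange needs of the synthetic-data exporter
# and the preprocessing loaders; not a general-purpose audio library.

#' Write a mono waveform to a WAV file
#'
#' @param samples Numeric vector of samples in `[-1, 1]` (clipped for PCM
#'   formats; stored verbatim for float formats).
#' @param path Output file path.
#' @param fs Sampling rate in Hz.
#' @param format One of `"float64"`, `"float32"`, `"pcm16"`, `"pcm24"`.
#'   `"float64"` round-trips R doubles bit-exactly.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(samples, path, fs,
                      format = c("float64", "float32", "pcm16", "pcm24")) {
  format <- match.arg(format)
  if (!is.numeric(samples) || length(samples) == 0L)
    stopf("`samples` must be a nonempty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("`fs` must be a positive sampling rate")
  n <- length(samples)
  spec <- switch(format,
    float64 = list(code = 3L, bits = 64L),
    float32 = list(code = 3L, bits = 32L),
    pcm16   = list(code = 1L, bits = 16L),
    pcm24   = list(code = 1L, bits = 24L))
  bytes_per <- spec$bits %/% 8L
  data_len <- n * bytes_per
  block_align <- bytes_per  # mono
  byte_rate <- as.integer(fs) * block_align

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_str <- function(s) writeBin(charToRaw(s), con)
  w_u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")

  has_fact <- spec$code == 3L
  riff_len <- 4L + (8L + 16L) + (if (has_fact) 8L + 4L else 0L) + 8L + data_len
  w_str("RIFF"); w_u32(riff_len); w_str("WAVE")
  w_str("fmt "); w_u32(16L)
  w_u16(spec$code); w_u16(1L)           # format code, channels
  w_u32(as.integer(fs)); w_u32(byte_rate)
  w_u16(block_align); w_u16(spec$bits)
  if (has_fact) { w_str("fact"); w_u32(4L); w_u32(n) }
  w_str("data"); w_u32(data_len)

  if (format == "float64") {
    writeBin(as.numeric(samples), con, size = 8L, endian = "little")
  } else if (format == "float32") {
    writeBin(as.numeric(samples), con, size = 4L, endian = "little")
  } else if (format == "pcm16") {
    x <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(x, con, size = 2L, endian = "little")
  } else { # pcm24
    x <- round(pmax(-1, pmin(1, samples)) * 8388607)
    x <- ifelse(x < 0, x + 16777216, x)  # two's complement in 3 bytes
    b <- rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Parses PCM 16/24-bit and IEEE float 32/64-bit mono files written by
#' [write_wav()] or other standard tools. PCM samples are rescaled to
#' `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return List with `samples` (numeric vector) and `fs` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  r_str <- function(n) rawToChar(readBin(con, "raw", n))
  r_u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  r_u16 <- function() readBin(con, "integer", 1L, size = 2L, endian = "little",
                              signed = FALSE)
  if (r_str(4L) != "RIFF") stopf("%s: not a RIFF file", path)
  r_u32()
  if (r_str(4L) != "WAVE") stopf("%s: not a WAVE file", path)

  fmt <- NULL; samples <- NULL
  repeat {
    id <- r_str(4L)
    if (length(id) == 0L || nchar(id) < 4L) break
    len <- r_u32()
    if (id == "fmt ") {
      fmt <- list(code = r_u16(), channels = r_u16(), fs = r_u32())
      r_u32(); r_u16()
      fmt$bits <- r_u16()
      if (len > 16L) readBin(con, "raw", len - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stopf("%s: data chunk before fmt chunk", path)
      if (fmt$channels != 1L) stopf("%s: only mono WAV supported", path)
      n <- len %/% (fmt$bits %/% 8L)
      if (fmt$code == 3L && fmt$bits == 64L) {
        samples <- readBin(con, "numeric", n, size = 8L, endian = "little")
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "numeric", n, size = 4L, endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", n, size = 2L, endian = "little") / 32767
      } else if (fmt$code == 1L && fmt$bits == 24L) {
        b <- as.integer(readBin(con, "raw", 3L * n))
        x <- b[c(TRUE, FALSE, FALSE)] + 256 * b[c(FALSE, TRUE, FALSE)] +
          65536 * b[c(FALSE, FALSE, TRUE)]
        x <- ifelse(x >= 8388608, x - 16777216, x)
        samples <- x / 8388607
      } else {
        stopf("%s: unsupported WAV format (code %d, %d bit)",
              path, fmt$code, fmt$bits)
      }
      break
    } else {
      readBin(con, "raw", len + len %% 2L)  # skip unknown chunk (padded)
    }
  }
  if (is.null(samples)) stopf("%s: no data chunk found", path)
  list(samples = samples, fs = fmt$fs)
}

## Raw little-endian float64 array IO with explicit dims (used by the dataset
## exporter; bit-exact round trip).
write_f64 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

read_f64 <- function(path, dim = NULL) {
  n <- file.size(path) %/% 8L
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "numeric", n, size = 8L, endian = "little")
  if (!is.null(dim)) dim(x) <- dim
  x
}
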