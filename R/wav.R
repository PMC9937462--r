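# Minimal RIFF/WAVE I/O: mono, 16-bit PCM or IEEE float32. Kept deliberately
# small; only the subset of the format the package reads and writes.

#' Write a mono WAV file
#'
#' @param samples numeric waveform with peak `|amplitude| <= 1`.
#' @param path output path.
#' @param sample_rate sampling rate in Hz.
#' @param format `"pcm16"` (16-bit integer) or `"float32"` (IEEE float).
#' @return invisibly, `path`.
#' @export
write_wav <- function(samples, path, sample_rate = 11025,
                      format = c("pcm16", "float32")) {
  format <- match.arg(format)
  n <- length(samples)
  bits <- if (format == "pcm16") 16L else 32L
  bytes <- bits %/% 8L
  audio_fmt <- if (format == "pcm16") 1L else 3L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")   # block align
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(clamp(samples, -1, 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Accepts the files [write_wav()] produces (and any mono PCM16/float32
#' RIFF/WAVE file); stereo or other encodings are rejected.
#'
#' @param path file path.
#' @return list with `samples` (numeric in \[-1, 1\]), `sample_rate`, and
#'   `format`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  audio_fmt <- NULL; channels <- NULL; sr <- NULL; bits <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      audio_fmt <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
    } else if (id == "data") {
      if (is.null(audio_fmt)) stop("data chunk before fmt", call. = FALSE)
      if (audio_fmt == 1 && bits == 16) {
        samples <- readBin(con, integer(), n = size %/% 2, size = 2,
                           signed = TRUE, endian = "little") / 32767
      } else if (audio_fmt == 3 && bits == 32) {
        samples <- readBin(con, numeric(), n = size %/% 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (only mono PCM16/float32)",
             call. = FALSE)
      }
      if (size %% 2 == 1) readBin(con, raw(), n = 1)
    } else {
      readBin(con, raw(), n = size + size %% 2)
    }
    if (!is.null(samples) && !is.null(sr)) break
  }
  if (is.null(samples)) stop("no data chunk found", call. = FALSE)
  if (!is.null(channels) && channels != 1)
    stop("only mono WAV input is supported (stereo rejected)", call. = FALSE)
  list(samples = samples, sample_rate = sr,
       format = if (audio_fmt == 1) "pcm16" else "float32")
}
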