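# Minimal RIFF/WAVE I/O: 16-bit PCM, mono. Kept self-contained so synthesized
# treatment sounds round-trip bit-identically.

#' Write a sound complex to a 16-bit PCM mono WAV file
#'
#' Samples are expected in `[-1, 1]`; values outside are clipped with a
#' warning. Quantization maps 1.0 to 32767.
#'
#' @param sound A `sound_complex`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(sound, path) {
  stopifnot(inherits(sound, "sound_complex"))
  x <- sound$samples
  if (any(abs(x) > 1)) {
    warning("samples outside [-1, 1] clipped on WAV export")
    x <- clamp(x, -1, 1)
  }
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(sound$fs_hz)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")        # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return A `sound_complex` with provenance `"raw"`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono supported", call. = FALSE)
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      bits <- readBin(con, "integer", 2, size = 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM supported", call. = FALSE)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", sz / 2, size = 2, signed = TRUE, endian = "little")
      return(sound_complex(pcm / 32767, fs, provenance = "raw"))
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
}
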