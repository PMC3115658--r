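# Minimal RIFF/WAVE I/O (16-bit PCM, interleaved multichannel). Kept
# deliberately small: enough to round-trip the generator's recordings.

#' Write a multichannel signal as a 16-bit PCM WAV file
#'
#' Samples are scaled by `scale` and clipped to [-1, 1) before
#' quantization; the default leaves amplitudes untouched.
#'
#' @param signal numeric vector or samples x channels matrix.
#' @param sample_rate Hz.
#' @param path output file.
#' @param scale linear gain applied before quantization.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, sample_rate, path, scale = 1) {
  x <- as.matrix(signal) * scale
  x <- pmin(pmax(x, -1), 1 - 1 / 32768)
  pcm <- as.integer(round(t(x) * 32767))          # interleave channels
  nch <- ncol(as.matrix(signal))
  byte_rate <- sample_rate * nch * 2L
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, nch), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(byte_rate, con, size = 4, endian = "little")
  writeBin(c(nch * 2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV file written by [write_wav()] or any canonical 16-bit
#'   PCM WAV.
#' @return list with `signal` (samples x channels matrix, in [-1, 1]) and
#'   `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data <- NULL; fs <- NULL; nch <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported", call. = FALSE)
      nch <- fmt[2]
      fs <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      rest <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (rest[2] != 16L) stop("only 16-bit PCM supported", call. = FALSE)
      if (sz > 16) invisible(readBin(con, raw(), sz - 16))
    } else if (id == "data") {
      data <- readBin(con, integer(), sz / 2, size = 2, endian = "little",
                      signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), sz))
    }
  }
  if (is.null(fs) || is.null(data)) stop("malformed WAV file", call. = FALSE)
  list(signal = t(matrix(data / 32767, nrow = nch)), sample_rate = fs)
}

#' Write crackle annotations as JSON lines
#'
#' One JSON record per crackle (times in ms, amplitudes in arbitrary
#' units, source location in cm).
#'
#' @param rec a `crackle_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation_jsonl <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  crk <- rec$crackles
  for (i in seq_len(NROW(crk))) {
    arr <- rec$arrivals[rec$arrivals$crackle == crk$crackle[i], ]
    rec_i <- c(as.list(crk[i, ]),
               list(arrivals = lapply(seq_len(nrow(arr)), function(j)
                 as.list(arr[j, c("channel", "onset_ms", "amplitude")]))))
    writeLines(jsonlite::toJSON(rec_i, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
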