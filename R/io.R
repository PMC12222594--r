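# Plain-text I/O: WAV audio, TSV matrices/envelopes/events with DCF
# ("key: value") sidecars.  All on-disk formats are text except WAV.

#' Read a RIFF WAV file
#'
#' Minimal reader for PCM 16-bit and IEEE float 32-bit WAV (mono or
#' multichannel; channels are averaged to mono on request).
#'
#' @param path file path
#' @param mono average channels to mono (default TRUE)
#' @return list with \code{samples} (numeric in [-1, 1] for PCM) and
#'   \code{fs}
#' @export
readWav <- function(path, mono = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("readWav: not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("readWav: not a WAVE file")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(code = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
                  channels = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
                  fs = readBin(con, "integer", 1, 4, endian = "little"))
      invisible(readBin(con, "integer", 1, 4, endian = "little")) # byte rate
      invisible(readBin(con, "integer", 1, 2, endian = "little")) # block align
      fmt$bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
      break
    } else invisible(readBin(con, "raw", sz))
  }
  if (is.null(fmt) || is.null(dat)) stop("readWav: missing fmt or data chunk")
  x <- if (fmt$code == 1 && fmt$bits == 16) {
    readBin(dat, "integer", length(dat) / 2, 2, endian = "little") / 32768
  } else if (fmt$code == 3 && fmt$bits == 32) {
    readBin(dat, "double", length(dat) / 4, 4, endian = "little")
  } else stop("readWav: unsupported encoding (PCM16 or float32 only)")
  if (fmt$channels > 1) {
    m <- matrix(x, nrow = fmt$channels)
    x <- if (mono) colMeans(m) else m
  }
  list(samples = x, fs = fmt$fs)
}

#' Write a PCM 16-bit WAV file
#'
#' @param samples numeric vector in [-1, 1] (clipped otherwise)
#' @param fs sampling rate, Hz
#' @param path output path
#' @return invisibly, the path
#' @export
writeWav <- function(samples, fs, path) {
  pcm <- as.integer(pmax(-1, pmin(1, samples)) * 32767)
  nBytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nBytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")          # PCM
  writeBin(1L, con, 2, endian = "little")          # mono
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 2), con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nBytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}

.writeSidecar <- function(path, fields) {
  write.dcf(as.data.frame(fields, check.names = FALSE), path)
}

.readSidecar <- function(path) {
  as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
}

#' Write/read an onset envelope as single-column TSV with a sidecar
#'
#' The sidecar (DCF "key: value" text next to the TSV, suffix
#' \code{.sidecar}) records the sampling rate, source id and processing
#' chain.
#'
#' @param env an [OnsetEnvelope-class]
#' @param path TSV path
#' @param chain free-text description of the processing chain
#' @return \code{writeEnvelopeTsv}: invisibly the path;
#'   \code{readEnvelopeTsv}: an [OnsetEnvelope-class]
#' @export
writeEnvelopeTsv <- function(env, path, chain = "unspecified") {
  stopifnot(is(env, "OnsetEnvelope"))
  write.table(data.frame(value = env@values), path, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  .writeSidecar(paste0(path, ".sidecar"),
                list(fs = env@fs, sourceId = env@sourceId, chain = chain))
  invisible(path)
}

#' @rdname writeEnvelopeTsv
#' @export
readEnvelopeTsv <- function(path) {
  v <- read.table(path, sep = "\t")[[1]]
  sc <- .readSidecar(paste0(path, ".sidecar"))
  new("OnsetEnvelope", values = as.numeric(v), fs = as.numeric(sc$fs),
      sourceId = as.character(sc$sourceId %||% "file"), pooledSigma = NA_real_,
      pulses = data.frame(timeS = numeric(0), amplitude = numeric(0)))
}

#' Write/read a multichannel recording as TSV with a sidecar
#'
#' Samples in rows, channels in columns (header row with channel labels);
#' the sidecar records sampling rate and reference state.
#'
#' @param rec a [ContinuousRecording-class]
#' @param path TSV path
#' @return \code{writeRecordingTsv}: invisibly the path;
#'   \code{readRecordingTsv}: a [ContinuousRecording-class]
#' @export
writeRecordingTsv <- function(rec, path) {
  stopifnot(is(rec, "ContinuousRecording"))
  m <- t(rec@data)
  colnames(m) <- rec@channels
  write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  .writeSidecar(paste0(path, ".sidecar"),
                list(fs = rec@fs, reference = rec@reference))
  invisible(path)
}

#' @rdname writeRecordingTsv
#' @export
readRecordingTsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
  sc <- .readSidecar(paste0(path, ".sidecar"))
  new("ContinuousRecording", data = t(m), fs = as.numeric(sc$fs),
      channels = colnames(m), reference = as.character(sc$reference %||% "unknown"))
}

#' Write/read trigger events as TSV
#'
#' Columns \code{onset_sample}, \code{stream}, \code{trial}; the format is
#' shared between the synthetic generator's ground truth and extracted
#' trigger sequences.
#'
#' @param events data.frame with columns onset_sample, stream, trial
#' @param path TSV path
#' @return \code{writeEventsTsv}: invisibly the path;
#'   \code{readEventsTsv}: the events data.frame
#' @export
writeEventsTsv <- function(events, path) {
  stopifnot(all(c("onset_sample", "stream", "trial") %in% names(events)))
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEventsTsv
#' @export
readEventsTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Export tidy attention-decoding measures
#'
#' Long-format TSV (subject, channel, condition, measure, value), the
#' exchange format for group-level statistics.
#'
#' @param measures data.frame with those columns
#' @param path TSV path
#' @return invisibly, the path
#' @export
writeMeasuresTsv <- function(measures, path) {
  need <- c("subject", "channel", "condition", "measure", "value")
  stopifnot(all(need %in% names(measures)))
  write.table(measures[need], path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
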