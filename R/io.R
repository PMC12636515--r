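# Record I/O: CSV with a JSON sidecar for labels/ground truth, and a minimal
# native WFDB subset (text .hea header, format-16 .dat signal, MIT-style
# annotation file for R peaks). No WFDB reader exists in the R ecosystem
# used here, so the subset below is implemented directly and round-trip
# tested; it covers single-signal format-16 records only.

#' Write a record as CSV plus JSON sidecar
#'
#' The CSV has columns `index` (0-based sample index), `mv` and `clean_mv`;
#' the sidecar `<path>.json` carries sampling rate, labels, seed, R peaks and
#' fiducials.
#'
#' @param record an `ecg_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  utils::write.csv(data.frame(index = seq_along(record$samples) - 1L,
                              mv = record$samples,
                              clean_mv = record$clean_samples),
                   path, row.names = FALSE)
  meta <- list(fs = record$fs, class_label = record$class_label,
               orientation_label = record$orientation_label,
               seed = record$seed, rpeaks = record$rpeaks,
               fiducials = record$fiducials)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a record written by [write_record_csv()]
#'
#' @param path CSV path (expects `<path>.json` alongside).
#' @return An `ecg_record`. Records read from disk carry no generator state,
#'   so operations that re-synthesize the waveform (pathology, position
#'   transforms) are not available on them.
#' @export
read_record_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  fid <- as.data.frame(meta$fiducials)
  new_record(d$mv, meta$fs,
             if ("clean_mv" %in% names(d)) d$clean_mv else d$mv,
             as.integer(meta$rpeaks), fid, meta$class_label,
             meta$orientation_label, meta$seed, gen = NULL)
}

WFDB_GAIN <- 200  # ADC units per mV

#' Write a record in WFDB format (minimal subset)
#'
#' Writes `<name>.hea` (text header), `<name>.dat` (format 16: 16-bit
#' little-endian two's complement at 200 adu/mV) and, when the record has R
#' peaks, `<name>.atr` (MIT annotation words, beat code N, with SKIP escapes
#' for long intervals). Amplitudes are quantized to 1/200 mV.
#'
#' @param record an `ecg_record`.
#' @param name record name (file stem).
#' @param dir output directory.
#' @return The header path, invisibly.
#' @export
write_record_wfdb <- function(record, name, dir = ".") {
  adc <- as.integer(pmax(pmin(round(record$samples * WFDB_GAIN), 32767), -32768))
  datfile <- paste0(name, ".dat")
  con <- file(file.path(dir, datfile), "wb")
  writeBin(adc, con, size = 2, endian = "little")
  close(con)
  checksum <- sum(adc) %% 65536
  if (checksum > 32767) checksum <- checksum - 65536
  hea <- c(sprintf("%s 1 %g %d", name, record$fs, length(adc)),
           sprintf("%s 16 %d 16 0 %d %d 0 ECG", datfile, WFDB_GAIN,
                   adc[1], checksum),
           sprintf("# class %s orientation %s", record$class_label,
                   record$orientation_label))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  if (length(record$rpeaks)) {
    write_wfdb_annotations(record$rpeaks, file.path(dir, paste0(name, ".atr")))
  }
  invisible(file.path(dir, paste0(name, ".hea")))
}

# MIT annotation stream: 16-bit words, (code << 10) | interval; SKIP (59)
# escapes intervals beyond 1023 samples with a 4-byte operand (high word
# first); terminated by a zero word. All annotations carry beat code N (1).
write_wfdb_annotations <- function(indices, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  words <- integer(0)
  for (i in indices) {
    delta <- i - prev
    if (delta > 1023L) {
      words <- c(words, bitwShiftL(59L, 10L),
                 bitwAnd(bitwShiftR(delta, 16L), 65535L),
                 bitwAnd(delta, 65535L))
      words <- c(words, bitwShiftL(1L, 10L))  # N with interval 0
    } else {
      words <- c(words, bitwOr(bitwShiftL(1L, 10L), delta))
    }
    prev <- i
  }
  words <- c(words, 0L)
  words[words > 32767L] <- words[words > 32767L] - 65536L
  writeBin(as.integer(words), con, size = 2, endian = "little")
  invisible(path)
}

read_wfdb_annotations <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  words <- readBin(con, integer(), n = sz / 2, size = 2, endian = "little")
  words[words < 0] <- words[words < 0] + 65536L
  out <- integer(0)
  cur <- 0L
  k <- 1L
  while (k <= length(words)) {
    w <- words[k]
    if (w == 0L) break
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (code == 59L) {
      delta <- bitwShiftL(words[k + 1L], 16L) + words[k + 2L]
      k <- k + 2L
      cur <- cur + delta
    } else {
      cur <- cur + delta
      out <- c(out, cur)
    }
    k <- k + 1L
  }
  out
}

#' Read a WFDB record written by [write_record_wfdb()]
#'
#' @param header path to the `.hea` file.
#' @return An `ecg_record` (no generator state; `clean_samples` equals the
#'   stored trace).
#' @export
read_record_wfdb <- function(header) {
  lines <- readLines(header)
  h1 <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  fs <- as.numeric(h1[3]); nsamp <- as.integer(h1[4])
  h2 <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  gain <- as.numeric(h2[3])
  datfile <- file.path(dirname(header), h2[1])
  con <- file(datfile, "rb")
  adc <- readBin(con, integer(), n = nsamp, size = 2, endian = "little")
  close(con)
  x <- adc / gain
  atr <- sub("\\.hea$", ".atr", header)
  rpeaks <- if (file.exists(atr)) read_wfdb_annotations(atr) else integer(0)
  lab <- "NR"; ori <- "O0"
  cm <- grep("^# class", lines, value = TRUE)
  if (length(cm)) {
    parts <- strsplit(cm[1], "\\s+")[[1]]
    lab <- parts[3]; ori <- parts[5]
  }
  new_record(x, fs, x, rpeaks,
             data.frame(), lab, ori, NA_integer_, gen = NULL)
}
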