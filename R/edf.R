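# Minimal EDF+ reader/writer (no R package in this stack handles EDF).
# Supports: continuous recordings ("EDF+C"), one sample rate across EEG
# signals, 16-bit samples, and one annotation stream holding
# (onset, duration, label) triplets as standard time-stamped annotation
# lists. Recordings are padded with zeros to a whole number of 1-s data
# records on write.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording as EDF+
#'
#' @param rec A `bb_recording`; annotations (if any) are stored in an
#'   "EDF Annotations" stream.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "bb_recording"))
  n_ch <- nrow(rec$data)
  sr <- rec$sr
  if (abs(sr - round(sr)) > 1e-9) stop("EDF writer needs an integer sample rate")
  sr <- as.integer(round(sr))
  n_rec <- as.integer(ceiling(ncol(rec$data) / sr))
  x <- rec$data
  if (ncol(x) < n_rec * sr) {
    x <- cbind(x, matrix(0, n_ch, n_rec * sr - ncol(x)))
  }
  pmax_v <- apply(abs(x), 1, max)
  pmax_v[pmax_v == 0] <- 1
  pmax_v <- signif(pmax_v * 1.0001, 6)
  # same affine map the reader inverts: [-pmax, pmax] -> [-32768, 32767]
  scale_v <- 2 * pmax_v / 65535
  dig <- round(sweep(sweep(x, 1, pmax_v, `+`), 1, scale_v, `/`)) - 32768
  ann_tals <- character(0)
  if (!is.null(rec$annotations) && nrow(rec$annotations) > 0) {
    a <- rec$annotations
    ann_tals <- sprintf("+%.6g\x15%.6g\x14%s\x14", a$onset_s, a$duration_s,
                        a$label)
  }
  has_ann <- TRUE   # always write the annotation stream (EDF+ requires it)
  # each record starts with its timekeeping TAL; all user annotations go
  # into the first record's stream
  ann_first <- paste0(sprintf("+0\x14\x14"), paste(ann_tals, collapse = ""))
  ann_bytes_per_rec <- 2L * ceiling((nchar(ann_first, type = "bytes") + 24) / 2)
  ann_spr <- ann_bytes_per_rec %/% 2L
  ns <- n_ch + has_ann
  con <- file(path, "wb")
  on.exit(close(con))
  wrt <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wrt("0", 8)
  wrt("X X X X", 80)
  wrt("Startdate X X X X", 80)
  wrt("01.01.00", 8)
  wrt("00.00.00", 8)
  wrt(256L * (1L + ns), 8)
  wrt("EDF+C", 44)
  wrt(n_rec, 8)
  wrt("1", 8)
  wrt(ns, 4)
  labels <- c(rec$channel_labels, if (has_ann) "EDF Annotations")
  for (l in labels) wrt(l, 16)
  for (i in seq_len(ns)) wrt("", 80)                    # transducer
  for (i in seq_len(ns)) wrt(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wrt(if (i <= n_ch) sprintf("%.6g", -pmax_v[i]) else "-1", 8)
  for (i in seq_len(ns)) wrt(if (i <= n_ch) sprintf("%.6g", pmax_v[i]) else "1", 8)
  for (i in seq_len(ns)) wrt("-32768", 8)
  for (i in seq_len(ns)) wrt("32767", 8)
  for (i in seq_len(ns)) wrt("", 80)                    # prefiltering
  for (i in seq_len(ns)) wrt(if (i <= n_ch) sr else ann_spr, 8)
  for (i in seq_len(ns)) wrt("", 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      writeBin(as.integer(dig[i, ((r - 1L) * sr + 1L):(r * sr)]), con,
               size = 2, endian = "little")
    }
    tal <- if (r == 1L) ann_first else sprintf("+%d\x14\x14", r - 1L)
    raw_tal <- charToRaw(tal)
    buf <- raw(2L * ann_spr)
    buf[seq_along(raw_tal)] <- raw_tal
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' @param path Input path.
#' @return A `bb_recording`. EEG signals must share one sample rate;
#'   annotations are returned as an (onset_s, duration_s, label) table.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)            # dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)
  is_ann <- labels == "EDF Annotations"
  eeg <- which(!is_ann)
  srs <- unique(spr[eeg] / rec_dur)
  if (length(srs) != 1) stop("sample rate differs across channels")
  data <- matrix(0, length(eeg), n_rec * spr[eeg[1]])
  ann_raw <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_ann[i]) {
        buf <- readBin(con, raw(), n = 2L * spr[i])
        ann_raw <- c(ann_raw, rawToChar(buf[buf != as.raw(0)]))
      } else {
        smp <- readBin(con, integer(), n = spr[i], size = 2, signed = TRUE,
                       endian = "little")
        j <- match(i, eeg)
        scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
        data[j, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
          pmin[i] + (smp - dmin[i]) * scale
      }
    }
  }
  annotations <- parse_tals(paste(ann_raw, collapse = ""))
  new_recording(data, srs, channel_labels = labels[eeg],
                annotations = annotations)
}

parse_tals <- function(txt) {
  if (!nzchar(txt)) return(NULL)
  tals <- strsplit(txt, "\x14\x14|\x14(?=\\+)|\x14(?=-)", perl = TRUE)[[1]]
  rows <- list()
  for (tal in tals) {
    parts <- strsplit(tal, "\x14")[[1]]
    head <- strsplit(parts[1], "\x15")[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    if (is.na(onset)) next
    duration <- if (length(head) > 1) as.numeric(head[2]) else NA_real_
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    for (l in labs) {
      rows[[length(rows) + 1L]] <- data.frame(
        onset_s = onset, duration_s = duration, label = l,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
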