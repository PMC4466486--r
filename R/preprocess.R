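#' Construct a multichannel recording
#'
#' @param data channels x samples matrix (microvolt).
#' @param sr Sample rate, Hz.
#' @param channel_labels Unique channel names (10-20 labels for real
#'   montages).
#' @param annotations Data frame with columns `onset_s`, `duration_s`,
#'   `label`, or `NULL`.
#' @return List of class `bb_recording`.
#' @export
new_recording <- function(data, sr, channel_labels = NULL,
                          annotations = NULL) {
  stopifnot(is.matrix(data), sr > 0)
  if (is.null(channel_labels)) {
    channel_labels <- default_channel_labels(nrow(data))
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (length(channel_labels) != nrow(data)) {
    stop("need one label per channel")
  }
  rownames(data) <- channel_labels
  if (!is.null(annotations)) {
    stopifnot(all(c("onset_s", "duration_s", "label") %in%
                    colnames(annotations)))
  }
  structure(list(data = data, sr = sr, channel_labels = channel_labels,
                 annotations = annotations),
            class = "bb_recording")
}

#' @export
print.bb_recording <- function(x, ...) {
  cat(sprintf("<bb_recording> %d channels x %d samples @ %g Hz (%.1f s), %d annotations\n",
              nrow(x$data), ncol(x$data), x$sr, ncol(x$data) / x$sr,
              if (is.null(x$annotations)) 0L else nrow(x$annotations)))
  invisible(x)
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero net phase), used to remove drifts before epoching. The default
#' 0.5 Hz cutoff matches the analysis chain's preprocessing.
#'
#' @param rec A `bb_recording`.
#' @param cutoff Cutoff frequency, Hz; must be below Nyquist.
#' @param order Butterworth order of the single pass.
#' @return Filtered `bb_recording`.
#' @export
highpass <- function(rec, cutoff = 0.5, order = 4) {
  stopifnot(inherits(rec, "bb_recording"))
  if (cutoff >= rec$sr / 2) {
    stop("cutoff ", cutoff, " Hz is at or above Nyquist (",
         rec$sr / 2, " Hz)")
  }
  bf <- signal::butter(order, cutoff / (rec$sr / 2), type = "high")
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) {
    signal::filtfilt(bf, ch)
  }))
  rownames(out$data) <- rec$channel_labels
  out
}

#' Anti-aliased resampling
#'
#' Polyphase FIR resampling to `target_sr`, annotations carried over
#' unchanged (they are stored in seconds).
#'
#' @param rec A `bb_recording`.
#' @param target_sr Target sample rate, Hz (must not exceed the current
#'   rate).
#' @return Resampled `bb_recording`.
#' @export
resample_recording <- function(rec, target_sr) {
  stopifnot(inherits(rec, "bb_recording"))
  if (target_sr <= 0) stop("target sample rate must be positive")
  if (target_sr > rec$sr) stop("upsampling is not supported")
  if (target_sr == rec$sr) return(rec)
  rat <- ratio_pq(target_sr, rec$sr)
  n_out <- round(ncol(rec$data) * target_sr / rec$sr)
  out <- rec
  out$data <- t(apply(rec$data, 1, function(ch) {
    y <- signal::resample(ch, p = rat[1], q = rat[2])
    length(y) <- n_out          # resample may over/undershoot by < 1 sample
    y[is.na(y)] <- 0
    y
  }))
  rownames(out$data) <- rec$channel_labels
  out$sr <- target_sr
  out
}

ratio_pq <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Extract condition epochs from an annotated recording
#'
#' Every annotation labelled `NB/blockXX` or `BB/blockXX` marks one
#' 60-s condition segment; the first and last `trim_s` seconds are
#' discarded to drop transient onset/offset responses, so the default
#' trim of 0.5 s turns a 60-s segment into a 59-s epoch. Condition,
#' beat frequency and band are resolved from the schedule by block
#' index.
#'
#' @param rec An annotated `bb_recording`.
#' @param schedule The [build_schedule()] table the session followed.
#' @param trim_s Seconds trimmed from each epoch edge.
#' @param keep_mask Optional logical vector, one entry per annotation,
#'   for rejecting artefactual epochs (all `TRUE` by default).
#' @return List of `bb_epoch`.
#' @export
extract_epochs <- function(rec, schedule, trim_s = 0.5, keep_mask = NULL) {
  stopifnot(inherits(rec, "bb_recording"))
  ann <- rec$annotations
  if (is.null(ann) || nrow(ann) == 0) stop("recording has no annotations")
  sel <- grepl("^(NB|BB)/block[0-9]+$", ann$label)
  ann <- ann[sel, , drop = FALSE]
  if (nrow(ann) == 0) stop("no NB/BB condition annotations found")
  if (is.null(keep_mask)) keep_mask <- rep(TRUE, nrow(ann))
  stopifnot(length(keep_mask) == nrow(ann))
  epochs <- list()
  for (i in seq_len(nrow(ann))) {
    if (!keep_mask[i]) next
    condition <- sub("/.*$", "", ann$label[i])
    blk <- as.integer(sub("^.*block", "", ann$label[i]))
    srow <- schedule[schedule$block_index == blk, , drop = FALSE]
    if (nrow(srow) != 1) {
      stop("annotation references block ", blk, " absent from the schedule")
    }
    if (ann$duration_s[i] < 2 * trim_s + 1 / rec$sr) {
      stop("segment of ", ann$duration_s[i], " s too short for a ",
           trim_s, " s edge trim")
    }
    i0 <- round((ann$onset_s[i] + trim_s) * rec$sr) + 1L
    n_samp <- round((ann$duration_s[i] - 2 * trim_s) * rec$sr)
    if (i0 + n_samp - 1L > ncol(rec$data)) {
      stop("annotation ", ann$label[i], " extends past the recording end")
    }
    epochs[[length(epochs) + 1L]] <- new_epoch(
      rec$data[, i0:(i0 + n_samp - 1L), drop = FALSE], rec$sr,
      condition = condition,
      f_bb = if (condition == "BB") srow$f_bb else NA_real_,
      band = srow$band, block_index = blk,
      channel_labels = rec$channel_labels)
  }
  epochs
}

#' Re-reference to the mean of named channels
#'
#' Subtracts the average of the named reference channels (for example
#' the two earlobe electrodes) from every channel.
#'
#' @param rec A `bb_recording`.
#' @param ref_labels Names of the reference channels.
#' @export
rereference <- function(rec, ref_labels) {
  stopifnot(inherits(rec, "bb_recording"))
  miss <- setdiff(ref_labels, rec$channel_labels)
  if (length(miss)) stop("unknown reference channels: ",
                         paste(miss, collapse = ", "))
  ref <- colMeans(rec$data[ref_labels, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2, ref)
  out
}

#' Standard 64-channel montage labels
#'
#' Extended 10-20 labels in Biosemi 64-electrode order, with schematic
#' 2-D layout coordinates (unit head radius, nose up) for topographic
#' displays. The layout is a conventional assumption, not a measured
#' digitization.
#'
#' @return Data frame with columns `label`, `x`, `y`.
#' @export
montage64 <- function() {
  path <- system.file("extdata", "montage64.tsv", package = "bbnet")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

default_channel_labels <- function(n) {
  if (n == 64) montage64()$label else sprintf("ch%02d", seq_len(n))
}
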