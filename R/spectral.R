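#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` at time-bandwidth
#' product `nw` from the eigenvectors of the standard symmetric
#' tridiagonal formulation. Tapers are unit-energy and ordered by
#' decreasing spectral concentration.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (default `2*nw - 1`).
#' @return n x k matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw = 4, k = 2 * nw - 1) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  cached <- .bbnet_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  t_idx <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_idx[-1] * (n - t_idx[-1]) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- diag_main
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  # fix sign: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    s <- sum(tapers[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tapers[, j] <- -tapers[, j]
    } else if (sum(tapers[seq_len(n %/% 2), j]) < 0) {
      tapers[, j] <- -tapers[, j]
    }
  }
  .bbnet_cache[[key]] <- tapers
  tapers
}

.bbnet_cache <- new.env(parent = emptyenv())

#' Multitaper power spectral density of an epoch
#'
#' The epoch is split into consecutive non-overlapping windows of
#' `nfft` samples (4 s at 256 Hz with the default 1024-point FFT); each
#' window is tapered with the first `2*nw - 1` Slepian sequences, the
#' tapered periodograms are averaged over tapers, and the window
#' estimates are averaged. The frequency grid has spacing `sr / nfft`
#' (0.25 Hz at the defaults).
#'
#' @param epoch A `bb_epoch` (or channels x samples matrix with an `sr`
#'   argument).
#' @param nw Time-bandwidth product.
#' @param nfft FFT length = window length in samples.
#' @param sr Sample rate; taken from the epoch when it is a `bb_epoch`.
#' @return List of class `bb_spectrum`: `freqs`, `psd`
#'   (channels x freqs, one-sided density), `nw`, `n_tapers`, `nfft`,
#'   `n_windows`, `sr`.
#' @export
multitaper_psd <- function(epoch, nw = 4, nfft = 1024, sr = NULL) {
  if (inherits(epoch, "bb_epoch")) {
    x <- epoch$data
    sr <- epoch$sr
  } else {
    x <- epoch
    if (is.null(sr)) stop("sr required when epoch is a plain matrix")
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  }
  n_samp <- ncol(x)
  if (n_samp < nfft) {
    stop("epoch of ", n_samp, " samples is shorter than one ", nfft,
         "-sample window")
  }
  n_win <- n_samp %/% nfft
  k <- 2 * nw - 1
  tapers <- dpss_tapers(nfft, nw, k)
  n_freq <- nfft %/% 2 + 1
  freqs <- (seq_len(n_freq) - 1) * sr / nfft
  scale <- c(1, rep(2, n_freq - 2), 1) / sr   # one-sided density
  psd <- matrix(0, nrow(x), n_freq)
  for (w in seq_len(n_win)) {
    seg <- x[, ((w - 1) * nfft + 1):(w * nfft), drop = FALSE]
    seg <- seg - rowMeans(seg)
    for (j in seq_len(k)) {
      Y <- stats::mvfft(t(seg * rep(tapers[, j], each = nrow(seg))))
      psd <- psd + t(abs(Y[seq_len(n_freq), , drop = FALSE])^2)
    }
  }
  psd <- sweep(psd / (n_win * k), 2, scale, `*`)
  rownames(psd) <- rownames(x)
  structure(list(freqs = freqs, psd = psd, nw = nw, n_tapers = k,
                 nfft = nfft, n_windows = n_win, sr = sr),
            class = "bb_spectrum")
}

#' @export
print.bb_spectrum <- function(x, ...) {
  cat(sprintf("<bb_spectrum> %d channels, %g-%g Hz @ %g Hz resolution (NW=%g, %d tapers, %d windows)\n",
              nrow(x$psd), min(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$nw, x$n_tapers, x$n_windows))
  invisible(x)
}

#' Mean band power per channel
#'
#' Mean of the PSD over the frequency bins inside the band, edges
#' inclusive on both sides (on the default 0.25 Hz grid the band edges
#' fall exactly on bins).
#'
#' @param spec A `bb_spectrum`.
#' @param band Band name (resolved via [bb_bands()]) or a list/row with
#'   `f_lo` and `f_hi`.
#' @return Named numeric vector, one value per channel.
#' @export
band_power <- function(spec, band) {
  stopifnot(inherits(spec, "bb_spectrum"))
  if (is.character(band)) {
    tab <- bb_bands("EEG")
    row <- tab[tab$name == band, ]
    if (nrow(row) != 1) stop("unknown EEG band: ", band)
    band <- row
  }
  sel <- spec$freqs >= band$f_lo & spec$freqs <= band$f_hi
  if (!any(sel)) stop("band ", band$f_lo, "-", band$f_hi,
                      " Hz contains no frequency bins")
  rowMeans(spec$psd[, sel, drop = FALSE])
}

#' Normalize binaural band power by the non-binaural baseline
#'
#' `10 * log10(bb / nb)` per channel: 0 dB means no change relative to
#' the non-binaural condition, +10 dB a tenfold power increase.
#'
#' @param bb,nb Per-channel linear band power under the binaural and
#'   non-binaural conditions (same channels, same order).
#' @return Per-channel normalized power in dB.
#' @export
normalize_power <- function(bb, nb) {
  stopifnot(length(bb) == length(nb))
  bad <- which(!(nb > 0))
  if (length(bad)) {
    nm <- if (!is.null(names(nb))) names(nb)[bad] else as.character(bad)
    stop("non-positive NB band power in channel(s): ",
         paste(nm, collapse = ", "))
  }
  10 * log10(bb / nb)
}

#' Normalized band-power table of a dataset
#'
#' For every subject, block and EEG band, computes the multitaper band
#' power of the BB epoch normalized by its own block's NB epoch,
#' per channel, and returns the tidy long table the statistical surface
#' consumes.
#'
#' @param dataset A `bb_dataset` (or list with `subjects` and `epochs`).
#' @param eeg_bands Band table, default [bb_bands()].
#' @param nw,nfft Multitaper parameters.
#' @return Data frame: `subject`, `group`, `electrode`, `eeg_band`,
#'   `bb_band`, `block_index`, `f_bb`, `value_db`.
#' @export
band_power_table <- function(dataset, eeg_bands = bb_bands("EEG"),
                             nw = 4, nfft = 1024) {
  grp <- stats::setNames(dataset$subjects$group, dataset$subjects$subject_id)
  rows <- list()
  eps <- dataset$epochs
  keys <- vapply(eps, function(e) paste(e$subject_id, e$block_index),
                 character(1))
  conds <- vapply(eps, function(e) e$condition, character(1))
  for (key in unique(keys)) {
    nb_i <- which(keys == key & conds == "NB")
    bb_i <- which(keys == key & conds == "BB")
    if (length(nb_i) != 1 || length(bb_i) != 1) {
      stop("block ", key, " does not have exactly one NB and one BB epoch")
    }
    nb_spec <- multitaper_psd(eps[[nb_i]], nw = nw, nfft = nfft)
    bb_spec <- multitaper_psd(eps[[bb_i]], nw = nw, nfft = nfft)
    e <- eps[[bb_i]]
    for (b in seq_len(nrow(eeg_bands))) {
      val <- normalize_power(band_power(bb_spec, eeg_bands[b, ]),
                             band_power(nb_spec, eeg_bands[b, ]))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = e$subject_id, group = unname(grp[e$subject_id]),
        electrode = rownames(e$data), eeg_band = eeg_bands$name[b],
        bb_band = e$band, block_index = e$block_index, f_bb = e$f_bb,
        value_db = unname(val), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Steady-state response per subject
#'
#' The SSR for a BB range is the normalized power in the matching EEG
#' band (alpha-EEG power under alpha-BB stimulation, and so on),
#' averaged over electrodes and over the blocks of that range.
#'
#' @param table Normalized table from [band_power_table()].
#' @param bb_band BB range name; the EEG band used is the same name.
#' @return Data frame: `subject`, `group`, `bb_band`, `value_db`.
#' @export
compute_ssr <- function(table, bb_band) {
  stopifnot(bb_band %in% band_levels)
  sub <- table[table$bb_band == bb_band & table$eeg_band == bb_band, ,
               drop = FALSE]
  if (nrow(sub) == 0) stop("no entries for BB range ", bb_band)
  agg <- stats::aggregate(value_db ~ subject + group, data = sub, FUN = mean)
  data.frame(subject = agg$subject, group = agg$group, bb_band = bb_band,
             value_db = agg$value_db, stringsAsFactors = FALSE)
}

#' Cross-band normalized power per subject
#'
#' Normalized power of one EEG band averaged over electrodes and blocks
#' of one (possibly different) BB range — e.g. alpha-EEG power during
#' delta-BB stimulation.
#'
#' @param table Normalized table from [band_power_table()].
#' @param eeg_band EEG analysis band.
#' @param bb_band BB stimulation range.
#' @return Data frame: `subject`, `group`, `eeg_band`, `bb_band`,
#'   `value_db`.
#' @export
cross_band_power <- function(table, eeg_band, bb_band) {
  sub <- table[table$bb_band == bb_band & table$eeg_band == eeg_band, ,
               drop = FALSE]
  if (nrow(sub) == 0) stop("no entries for ", eeg_band, " x ", bb_band)
  agg <- stats::aggregate(value_db ~ subject + group, data = sub, FUN = mean)
  data.frame(subject = agg$subject, group = agg$group,
             eeg_band = eeg_band, bb_band = bb_band,
             value_db = agg$value_db, stringsAsFactors = FALSE)
}
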