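#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR applied forward and
#' backward, so the net phase response is zero — a requirement for
#' phase-synchrony analysis, where any phase distortion would bias the
#' relative-phase statistics. The filter order is the smallest even
#' integer covering three cycles of the band's lower edge.
#'
#' @param epoch A `bb_epoch` or channels x samples matrix.
#' @param band EEG band name or a list/row with `f_lo`, `f_hi`.
#' @param sr Sample rate; taken from the epoch when it is a `bb_epoch`.
#' @return Object of the same shape with filtered data.
#' @export
bandpass_zerophase <- function(epoch, band, sr = NULL) {
  if (inherits(epoch, "bb_epoch")) {
    x <- epoch$data
    sr <- epoch$sr
  } else {
    x <- epoch
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (is.null(sr)) stop("sr required when epoch is a plain matrix")
  }
  if (is.character(band)) {
    tab <- bb_bands("EEG")
    row <- tab[tab$name == band, ]
    if (nrow(row) != 1) stop("unknown EEG band: ", band)
    band <- row
  }
  if (band$f_hi >= sr / 2) {
    stop("band upper edge ", band$f_hi, " Hz is at or above Nyquist")
  }
  ord <- ceiling(3 * sr / band$f_lo)
  if (ord %% 2 == 1) ord <- ord + 1
  if (ord + 1 >= ncol(x)) stop("epoch too short for the filter order")
  b <- signal::fir1(ord, c(band$f_lo, band$f_hi) / (sr / 2), type = "pass")
  y <- t(apply(x, 1, function(ch) signal::filtfilt(b, ch)))
  rownames(y) <- rownames(x)
  if (inherits(epoch, "bb_epoch")) {
    out <- epoch
    out$data <- y
    out
  } else {
    y
  }
}

# Analytic signal via the frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrowband epoch
#'
#' Converts each (already band-passed) channel into its analytic signal
#' via the Hilbert transform and extracts the four-quadrant
#' instantaneous phase in (-pi, pi]. Samples within `edge_s` seconds of
#' either epoch edge are excluded from `valid_mask` to drop filter and
#' Hilbert transients.
#'
#' @param epoch A `bb_epoch` or channels x samples matrix of
#'   narrowband data.
#' @param sr Sample rate for plain matrices.
#' @param edge_s Seconds excluded at each edge.
#' @return List of class `bb_phase`: `theta` (channels x samples,
#'   radians), `valid_mask` (logical per sample), `sr`.
#' @export
analytic_phase <- function(epoch, sr = NULL, edge_s = 1) {
  if (inherits(epoch, "bb_epoch")) {
    x <- epoch$data
    sr <- epoch$sr
  } else {
    x <- epoch
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (is.null(sr)) stop("sr required when epoch is a plain matrix")
  }
  if (any(apply(x, 1, function(ch) all(ch == 0)))) {
    stop("all-zero channel: instantaneous phase is undefined")
  }
  theta <- t(apply(x, 1, function(ch) {
    z <- analytic_signal(ch)
    atan2(Im(z), Re(z))
  }))
  rownames(theta) <- rownames(x)
  n <- ncol(theta)
  n_edge <- round(edge_s * sr)
  valid <- rep(TRUE, n)
  if (n_edge > 0) {
    if (2 * n_edge >= n) stop("edge exclusion longer than the epoch")
    valid[c(seq_len(n_edge), (n - n_edge + 1):n)] <- FALSE
  }
  structure(list(theta = theta, valid_mask = valid, sr = sr),
            class = "bb_phase")
}

#' Cyclic relative phase of two channels
#'
#' Signed phase difference `theta_i - theta_k` wrapped to [0, 2*pi).
#' The wrap preserves the sign information `sin(phi)` needs, so a lead
#' of pi/4 and a lag of pi/4 map to pi/4 and 7*pi/4 respectively.
#'
#' @param theta_i,theta_k Phase vectors in radians (equal length).
#' @return Numeric vector of relative phases in [0, 2*pi).
#' @export
relative_phase <- function(theta_i, theta_k) {
  if (length(theta_i) != length(theta_k)) {
    stop("phase series differ in length")
  }
  (theta_i - theta_k) %% (2 * pi)
}

#' Phase locking value
#'
#' Modulus of the time-averaged unit phasor of the relative phase:
#' 1 when the relative phase is constant (phase locked at any lag),
#' near 0 when it spreads uniformly over the circle.
#'
#' @param phi Relative phase samples (radians).
#' @return Value in [0, 1].
#' @export
plv <- function(phi) {
  if (length(phi) < 2) stop("need at least 2 phase samples")
  Mod(mean(exp(1i * phi)))
}

#' Phase lag index
#'
#' Modulus of the time-averaged sign of the sine of the relative phase,
#' with `sign(0) = 0`. Insensitive to zero-lag synchrony: a relative
#' phase concentrated at 0 (or pi) — the signature of volume conduction
#' — gives 0, while a consistent non-zero lag gives values up to 1.
#'
#' @param phi Relative phase samples (radians).
#' @return Value in [0, 1].
#' @export
pli <- function(phi) {
  if (length(phi) < 2) stop("need at least 2 phase samples")
  abs(mean(sign(sin(phi))))
}

#' Phase-synchrony adjacency matrix of an epoch
#'
#' Band-pass filters the epoch, extracts instantaneous phases, and
#' computes the chosen synchrony index for all channel pairs. The
#' result is symmetric with zero diagonal and entries in [0, 1].
#'
#' @param epoch A `bb_epoch`.
#' @param band EEG band name.
#' @param method `"PLV"` or `"PLI"`.
#' @param edge_s Edge exclusion passed to [analytic_phase()].
#' @return Object of class `bb_adjacency`: list with `a` (n x n
#'   matrix), `method`, `band`, `condition`, `bb_band`, `f_bb`,
#'   `subject_id`.
#' @export
build_adjacency <- function(epoch, band, method = c("PLV", "PLI"),
                            edge_s = 1) {
  method <- match.arg(method)
  stopifnot(inherits(epoch, "bb_epoch"))
  if (nrow(epoch$data) < 2) stop("need at least 2 channels")
  filt <- bandpass_zerophase(epoch, band)
  ph <- analytic_phase(filt, edge_s = edge_s)
  adjacency_from_phase(ph, method = method,
                       band = if (is.character(band)) band else band$name,
                       condition = epoch$condition, bb_band = epoch$band,
                       f_bb = epoch$f_bb, subject_id = epoch$subject_id)
}

#' Adjacency matrix from a precomputed phase series
#'
#' @param ph A `bb_phase`.
#' @param method `"PLV"` or `"PLI"`.
#' @param band,condition,bb_band,f_bb,subject_id Metadata carried on
#'   the result.
#' @export
adjacency_from_phase <- function(ph, method = c("PLV", "PLI"),
                                 band = NA_character_,
                                 condition = NA_character_,
                                 bb_band = NA_character_,
                                 f_bb = NA_real_,
                                 subject_id = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(ph, "bb_phase"))
  th <- ph$theta[, ph$valid_mask, drop = FALSE]
  n <- nrow(th)
  # vectorized over pairs: both indices are averages of pairwise phasor
  # functions, computable from the channel phasor matrix
  z <- exp(1i * th)
  if (method == "PLV") {
    a <- Mod(tcrossprod(z, Conj(z))) / ncol(th)
  } else {
    # sign(sin(theta_i - theta_k)) summed over time for all pairs
    a <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      d <- th[i, ] - t(th[(i + 1):n, , drop = FALSE])
      s <- colMeans(sign(sin(d)))
      a[i, (i + 1):n] <- abs(s)
    }
    a <- a + t(a)
  }
  diag(a) <- 0
  a[a > 1] <- 1
  dimnames(a) <- list(rownames(ph$theta), rownames(ph$theta))
  structure(list(a = a, method = method, band = band,
                 condition = condition, bb_band = bb_band, f_bb = f_bb,
                 subject_id = subject_id),
            class = "bb_adjacency")
}

#' @export
print.bb_adjacency <- function(x, ...) {
  cat(sprintf("<bb_adjacency> %s | %d nodes | band=%s condition=%s bb_band=%s subject=%s\n",
              x$method, nrow(x$a), x$band, x$condition, x$bb_band,
              x$subject_id))
  invisible(x)
}

#' Average adjacency matrices
#'
#' Element-wise mean of matrices from the blocks of one BB range (the
#' aggregation used before group statistics). All matrices must share
#' method, band and dimensions.
#'
#' @param adj_list List of `bb_adjacency`.
#' @return A `bb_adjacency` with averaged weights.
#' @export
average_adjacency <- function(adj_list) {
  stopifnot(length(adj_list) >= 1,
            all(vapply(adj_list, inherits, logical(1), "bb_adjacency")))
  m <- unique(vapply(adj_list, `[[`, character(1), "method"))
  bd <- unique(vapply(adj_list, `[[`, character(1), "band"))
  if (length(m) != 1 || length(bd) != 1) {
    stop("cannot average adjacency matrices of mixed method or band")
  }
  a <- Reduce(`+`, lapply(adj_list, `[[`, "a")) / length(adj_list)
  out <- adj_list[[1]]
  out$a <- a
  out$f_bb <- NA_real_
  out
}

#' Write an adjacency matrix as TSV with a JSON sidecar
#' @param adj A `bb_adjacency`.
#' @param path Output TSV path (`.json` sidecar written alongside).
#' @param k_density Density recorded in the sidecar (1 = unthresholded).
#' @export
write_adjacency_tsv <- function(adj, path, k_density = 1) {
  utils::write.table(adj$a, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = colnames(adj$a))
  meta <- list(method = adj$method, band = adj$band,
               condition = adj$condition, bb_band = adj$bb_band,
               density = k_density)
  jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
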