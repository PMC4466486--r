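#' Global network-metrics table of a dataset
#'
#' For every subject, condition and BB range: per-block adjacency
#' matrices in the analysis band are averaged, thresholded at each
#' density of the grid, and summarized by global strength, clustering
#' and local efficiency — one row per subject x condition x range x
#' method x density.
#'
#' @param dataset A `bb_dataset`.
#' @param config A `bb_config`.
#' @return Tidy data frame: `subject`, `group`, `method`, `band`,
#'   `condition`, `bb_band`, `k_density`, `S`, `C`, `E`.
#' @export
metrics_table <- function(dataset, config = default_config()) {
  grp <- stats::setNames(dataset$subjects$group, dataset$subjects$subject_id)
  band <- config$analysis_band
  # adjacency per epoch (phases computed once, reused by both methods)
  adj <- list()
  for (e in dataset$epochs) {
    filt <- bandpass_zerophase(e, band)
    ph <- analytic_phase(filt)
    for (m in config$methods) {
      adj[[length(adj) + 1L]] <- adjacency_from_phase(
        ph, method = m, band = band, condition = e$condition,
        bb_band = e$band, f_bb = e$f_bb, subject_id = e$subject_id)
    }
  }
  key <- vapply(adj, function(a) paste(a$subject_id, a$condition,
                                       a$bb_band, a$method, sep = "|"),
                character(1))
  rows <- list()
  for (kk in unique(key)) {
    avg <- average_adjacency(adj[key == kk])
    for (k in config$k_density_grid) {
      gm <- network_metrics(threshold_fixed_density(avg, k))$global
      gm$group <- unname(grp[gm$subject])
      rows[[length(rows) + 1L]] <- gm
    }
  }
  out <- do.call(rbind, rows)
  out[, c("subject", "group", "method", "band", "condition", "bb_band",
          "k_density", "S", "C", "E")]
}

#' End-to-end analysis of a binaural-beat dataset
#'
#' Runs the full chain on an epoch dataset: multitaper band power with
#' non-binaural normalization, SSR extraction, phase-synchrony
#' adjacency matrices (PLV and PLI), fixed-density network metrics over
#' the density grid, and the mixed-ANOVA contrast battery.
#'
#' @param dataset A `bb_dataset` (from [generate_dataset()] or built
#'   from read epochs via [as_bb_dataset()]).
#' @param config A `bb_config`.
#' @return Object of class `bb_analysis` with elements `power_table`,
#'   `metrics`, `contrasts`, `config`, `subjects`.
#' @examples
#' \donttest{
#' sched <- build_schedule()[c(1, 9, 17, 25, 30), ]
#' ds <- generate_dataset(2, schedule = sched, n_channels = 8,
#'                        duration_s = 8, seed = 42)
#' fit <- bb_analyze(ds)
#' summary(fit)
#' }
#' @export
bb_analyze <- function(dataset, config = default_config()) {
  stopifnot(inherits(dataset, "bb_dataset") || is.list(dataset))
  pt <- band_power_table(dataset, nw = config$nw, nfft = config$nfft)
  mt <- metrics_table(dataset, config)
  ct <- run_contrast_battery(pt, mt)
  structure(list(power_table = pt, metrics = mt, contrasts = ct,
                 config = config, subjects = dataset$subjects),
            class = "bb_analysis")
}

#' Wrap a list of epochs as a dataset
#'
#' @param epochs List of `bb_epoch` with subject ids set.
#' @param subjects Data frame with `subject_id` and `group`; inferred
#'   as a single "nonmusician" group when omitted.
#' @export
as_bb_dataset <- function(epochs, subjects = NULL) {
  ids <- unique(vapply(epochs, function(e) e$subject_id, character(1)))
  if (is.null(subjects)) {
    subjects <- data.frame(subject_id = ids, group = "nonmusician",
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(ids %in% subjects$subject_id))
  structure(list(subjects = subjects, epochs = epochs,
                 ground_truth = NULL),
            class = "bb_dataset")
}

#' @export
print.bb_analysis <- function(x, ...) {
  cat(sprintf("<bb_analysis> %d subjects, %d power rows, %d metric rows\n",
              nrow(x$subjects), nrow(x$power_table), nrow(x$metrics)))
  cat(sprintf("analysis band: %s | methods: %s | densities: %s\n",
              x$config$analysis_band,
              paste(x$config$methods, collapse = ", "),
              paste(x$config$k_density_grid, collapse = ", ")))
  invisible(x)
}

#' @export
summary.bb_analysis <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$contrasts)
  invisible(object)
}

#' Plot a fitted binaural-beat analysis
#'
#' `which = "power"` shows mean normalized alpha power per BB range
#' with standard-error bars; `which = "network"` shows PLI global
#' strength for NB vs BB per range, split by group, at the largest
#' density of the grid.
#'
#' @param x A `bb_analysis`.
#' @param which `"power"` or `"network"`.
#' @param ... Unused.
#' @export
plot.bb_analysis <- function(x, which = c("power", "network"), ...) {
  which <- match.arg(which)
  if (which == "power") {
    present <- intersect(band_levels, unique(x$power_table$bb_band))
    cb <- do.call(rbind, lapply(present, function(b) {
      cross_band_power(x$power_table, "alpha", b)
    }))
    mu <- tapply(cb$value_db, factor(cb$bb_band, present), mean)
    se <- tapply(cb$value_db, factor(cb$bb_band, present),
                 function(v) stats::sd(v) / sqrt(length(v)))
    bp <- graphics::barplot(mu, ylab = "normalized alpha power (dB)",
                            xlab = "BB range",
                            ylim = range(0, mu + 2 * se, mu - 2 * se))
    graphics::arrows(bp, mu - se, bp, mu + se, angle = 90, code = 3,
                     length = 0.05)
    graphics::abline(h = 0, lty = 2)
  } else {
    k <- max(x$config$k_density_grid)
    m <- x$metrics[x$metrics$method == "PLI" & x$metrics$k_density == k, ]
    mu <- tapply(m$S, list(factor(m$condition, c("NB", "BB")),
                           factor(m$bb_band, band_levels),
                           m$group), mean)
    op <- graphics::par(mfrow = c(1, dim(mu)[3]))
    on.exit(graphics::par(op))
    for (g in dimnames(mu)[[3]]) {
      graphics::barplot(mu[, , g], beside = TRUE,
                        legend.text = c("NB", "BB"), main = g,
                        ylab = sprintf("PLI strength (k=%g)", k),
                        xlab = "BB range")
    }
  }
  invisible(x)
}
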