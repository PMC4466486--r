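#' One-sample t-test
#'
#' Two-tailed one-sample t-test against `mu0`, reported in the
#' `effect / statistic / df / p` shape used throughout the results
#' surface.
#'
#' @param values Numeric vector (n >= 2).
#' @param mu0 Null mean.
#' @param effect Label carried on the result row.
#' @return One-row data frame: `effect`, `statistic`, `df1`, `df2`, `p`.
#' @export
one_sample_t <- function(values, mu0 = 0, effect = "one-sample") {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) stop("zero variance: t is undefined")
  tt <- stats::t.test(values, mu = mu0)
  data.frame(effect = effect, statistic = unname(tt$statistic),
             df1 = NA_real_, df2 = unname(tt$parameter),
             p = tt$p.value, stringsAsFactors = FALSE)
}

#' Paired t-test
#' @param x,y Paired numeric vectors of equal length.
#' @param effect Label carried on the result row.
#' @return One-row data frame as in [one_sample_t()].
#' @export
paired_t <- function(x, y, effect = "paired") {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) stop("zero variance of differences: t is undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  data.frame(effect = effect, statistic = unname(tt$statistic),
             df1 = NA_real_, df2 = unname(tt$parameter),
             p = tt$p.value, stringsAsFactors = FALSE)
}

#' Unpaired t-test (pooled variance)
#'
#' Classical two-sample t with pooled variance, df = n1 + n2 - 2,
#' matching the group comparisons of the reported analyses.
#'
#' @param x,y Numeric vectors (each n >= 2).
#' @param effect Label carried on the result row.
#' @return One-row data frame as in [one_sample_t()].
#' @export
unpaired_t <- function(x, y, effect = "unpaired") {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) {
    stop("zero variance in both groups: t is undefined")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  data.frame(effect = effect, statistic = unname(tt$statistic),
             df1 = NA_real_, df2 = unname(tt$parameter),
             p = tt$p.value, stringsAsFactors = FALSE)
}

#' Mixed factorial ANOVA
#'
#' Univariate mixed-model ANOVA with one between-subject factor and one
#' or two within-subject factors, subject treated as a random factor
#' nested in the between groups. Each within effect is tested against
#' its own subject-interaction error stratum, so for the full
#' 2 (Group) x 2 (Beat) x 5 (Range) design with 32 subjects the
#' Beat x Range error has (32 - 2) * 1 * 4 = 120 degrees of freedom.
#' No sphericity correction is applied.
#'
#' @param data Long-format data frame, one row per subject x within
#'   cell; the design must be balanced and complete.
#' @param dv Name of the dependent-variable column.
#' @param between Name of the between-subject factor column.
#' @param within Character vector (length 1 or 2) of within-subject
#'   factor columns.
#' @param subject Name of the subject identifier column.
#' @return Data frame with one row per effect: `effect`, `statistic`
#'   (F), `df1`, `df2`, `p`.
#' @export
mixed_anova <- function(data, dv = "value", between = "group",
                        within = c("beat", "range"), subject = "subject") {
  stopifnot(all(c(dv, between, within, subject) %in% names(data)))
  d <- data
  d$.dv <- d[[dv]]
  d$.grp <- factor(d[[between]])
  d$.subj <- factor(d[[subject]])
  for (i in seq_along(within)) {
    d[[paste0(".w", i)]] <- factor(d[[within[i]]])
  }
  wvars <- paste0(".w", seq_along(within))
  # balance check: every subject must have every within-cell exactly once
  cells <- table(d$.subj, interaction(d[, wvars, drop = FALSE]))
  if (any(cells != 1)) stop("design is unbalanced or has missing cells")
  # a single-level between factor degenerates to a pure within design
  grp_terms <- if (nlevels(d$.grp) >= 2) ".grp" else character(0)
  rhs <- paste(c(grp_terms, wvars), collapse = " * ")
  err <- paste0("Error(.subj/(", paste(wvars, collapse = " * "), "))")
  form <- stats::as.formula(paste(".dv ~", rhs, "+", err))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- rownames(tab)
    res_i <- grep("^Residuals", trimws(terms))
    if (length(res_i) != 1) next
    df_err <- tab$Df[res_i]
    for (i in setdiff(seq_along(terms), res_i)) {
      f_val <- tab$`F value`[i]
      p_val <- tab$`Pr(>F)`[i]
      if (is.nan(f_val)) {
        # degenerate 0/0 on constant data: no effect by convention
        f_val <- 0
        p_val <- 1
      }
      if (is.na(f_val)) next
      nm <- trimws(terms[i])
      nm <- gsub("\\.grp", between, nm)
      for (j in seq_along(within)) {
        nm <- gsub(paste0("\\.w", j), within[j], nm)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = nm, statistic = f_val,
        df1 = tab$Df[i], df2 = df_err, p = p_val,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # constant response: every SS is numerical fuzz; no effect by convention
  if (stats::var(d$.dv) <= 1e-20 * (1 + mean(d$.dv)^2)) {
    out$statistic <- 0
    out$p <- 1
  }
  out
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false-discovery-rate control: p-values are BH-adjusted and
#' every electrode whose adjusted p is at most `q` is flagged. The
#' resulting mask is identical to applying the step-up rule directly
#' (largest rank i with p_(i) <= (i/m) q, reject all smaller ranks).
#'
#' @param pvals Vector of p-values in [0, 1].
#' @param q FDR level.
#' @return List of class `bb_fdr`: `mask` (logical), `p_adj`, `q`.
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) stop("empty p-value vector")
  stopifnot(all(pvals >= 0 & pvals <= 1))
  p_adj <- stats::p.adjust(pvals, method = "BH")
  structure(list(mask = p_adj <= q, p_adj = p_adj, q = q),
            class = "bb_fdr")
}

#' Electrode-level topography test with FDR correction
#'
#' Runs one t-test per electrode — paired between two within-subject
#' condition matrices, or unpaired between two group matrices — and
#' applies Benjamini-Hochberg FDR over electrodes.
#'
#' @param x,y subjects x electrodes matrices (equal electrode sets;
#'   equal subject count if `paired`).
#' @param paired Paired (condition contrast) or unpaired (group
#'   contrast) test.
#' @param q FDR level (0.05 for global maps, 0.1 for the local maps).
#' @return Data frame: `electrode`, `statistic`, `df`, `p`, `p_adj`,
#'   `significant`.
#' @export
topography_test <- function(x, y, paired = TRUE, q = 0.1) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == ncol(y))
  res <- lapply(seq_len(ncol(x)), function(e) {
    if (paired) paired_t(x[, e], y[, e]) else unpaired_t(x[, e], y[, e])
  })
  res <- do.call(rbind, res)
  fdr <- fdr_correct(res$p, q)
  data.frame(
    electrode = if (!is.null(colnames(x))) colnames(x)
                else sprintf("e%02d", seq_len(ncol(x))),
    statistic = res$statistic, df = res$df2, p = res$p,
    p_adj = fdr$p_adj, significant = fdr$mask,
    stringsAsFactors = FALSE)
}

#' Mann-Whitney rank-sum test (normal approximation)
#'
#' Utility for behavioural group comparisons; not part of the main
#' pipeline.
#'
#' @param x,y Numeric vectors.
#' @return One-row data frame: `effect`, `statistic` (z), `df1`, `df2`,
#'   `p`.
#' @export
mann_whitney <- function(x, y) {
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  n1 <- length(x); n2 <- length(y)
  mu <- n1 * n2 / 2
  sd_u <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  z <- (unname(wt$statistic) - mu) / sd_u
  data.frame(effect = "group (rank-sum)", statistic = z,
             df1 = NA_real_, df2 = NA_real_, p = wt$p.value,
             stringsAsFactors = FALSE)
}

#' Run the full contrast battery
#'
#' Reproduces the study's test structure on a dataset's derived tables:
#' the 2 x 2 SSR ANOVA (Group x BeatFrequency alpha/gamma), one-sample
#' SSR t-tests per range, the 2 x 5 ANOVA of normalized alpha power
#' over BB ranges, per-measure 2 x 2 x 5 mixed ANOVAs of the global
#' network metrics at every density, and the musicians' BB-minus-NB
#' paired contrast of the PLI metrics in the theta/alpha ranges.
#'
#' @param power_table Normalized power table from [band_power_table()].
#' @param metrics_table Tidy global-metrics table with columns
#'   `subject`, `group`, `method`, `band`, `condition`, `bb_band`,
#'   `k_density`, `S`, `C`, `E`.
#' @param alpha_level Significance level used to flag effects.
#' @return List of class `bb_contrasts`.
#' @export
run_contrast_battery <- function(power_table, metrics_table,
                                alpha_level = 0.05) {
  present <- unique(power_table$bb_band)
  ssr_bands <- intersect(c("alpha", "gamma"), present)
  ssr <- do.call(rbind, lapply(ssr_bands, function(b) {
    compute_ssr(power_table, b)
  }))
  ssr$beatfreq <- ssr$bb_band
  ssr_anova <- if (length(ssr_bands) == 2) {
    mixed_anova(ssr, dv = "value_db", between = "group",
                within = "beatfreq")
  }
  ssr_t <- do.call(rbind, lapply(ssr_bands, function(b) {
    v <- ssr$value_db[ssr$bb_band == b]
    one_sample_t(v, 0, effect = paste0(b, "-BB SSR"))
  }))
  cross <- do.call(rbind, lapply(intersect(band_levels, present),
                                 function(b) {
    cross_band_power(power_table, "alpha", b)
  }))
  alpha_power_anova <- if (length(unique(cross$bb_band)) >= 2) {
    mixed_anova(cross, dv = "value_db", between = "group",
                within = "bb_band")
  }
  net_anova <- NULL
  for (m in unique(metrics_table$method)) {
    for (k in unique(metrics_table$k_density)) {
      sub <- metrics_table[metrics_table$method == m &
                             metrics_table$k_density == k, ]
      wvars <- if (length(unique(sub$bb_band)) >= 2) {
        c("condition", "bb_band")
      } else "condition"
      for (measure in c("S", "C", "E")) {
        an <- mixed_anova(sub, dv = measure, between = "group",
                          within = wvars)
        an$method <- m; an$k_density <- k; an$measure <- measure
        net_anova <- rbind(net_anova, an)
      }
    }
  }
  musician <- NULL
  pli <- metrics_table[metrics_table$method == "PLI", ]
  for (k in unique(pli$k_density)) {
    for (b in intersect(c("theta", "alpha"), unique(pli$bb_band))) {
      for (g in unique(pli$group)) {
        sub <- pli[pli$k_density == k & pli$bb_band == b & pli$group == g, ]
        bb <- sub$S[sub$condition == "BB"][order(sub$subject[sub$condition == "BB"])]
        nb <- sub$S[sub$condition == "NB"][order(sub$subject[sub$condition == "NB"])]
        tt <- paired_t(bb, nb, effect = sprintf(
          "PLI S BB-NB | %s, %s-BB, k=%g", g, b, k))
        tt$group <- g; tt$bb_band <- b; tt$k_density <- k
        tt$mean_diff <- mean(bb - nb)
        musician <- rbind(musician, tt)
      }
    }
  }
  structure(list(ssr_anova = ssr_anova, ssr_t = ssr_t,
                 alpha_power_anova = alpha_power_anova,
                 network_anova = net_anova,
                 musician_contrast = musician,
                 alpha_level = alpha_level),
            class = "bb_contrasts")
}

#' @export
print.bb_contrasts <- function(x, ...) {
  fmt <- function(df) {
    df$p <- signif(df$p, 3)
    df$statistic <- round(df$statistic, 3)
    df
  }
  if (!is.null(x$ssr_anova)) {
    cat("== SSR ANOVA (Group x BeatFrequency alpha/gamma) ==\n")
    print(fmt(x$ssr_anova), row.names = FALSE)
  }
  if (!is.null(x$ssr_t)) {
    cat("\n== One-sample SSR t-tests ==\n")
    print(fmt(x$ssr_t), row.names = FALSE)
  }
  if (!is.null(x$alpha_power_anova)) {
    cat("\n== Normalized alpha power ANOVA (Group x BB range) ==\n")
    print(fmt(x$alpha_power_anova), row.names = FALSE)
  }
  if (!is.null(x$network_anova)) {
    sig <- x$network_anova[x$network_anova$p < x$alpha_level, ]
    cat(sprintf("\n== Network ANOVAs: %d of %d effects with p < %g ==\n",
                nrow(sig), nrow(x$network_anova), x$alpha_level))
    if (nrow(sig)) print(fmt(sig), row.names = FALSE)
  }
  if (!is.null(x$musician_contrast)) {
    cat("\n== PLI strength BB-NB paired contrasts ==\n")
    print(fmt(x$musician_contrast[, c("effect", "statistic", "df2", "p",
                                      "mean_diff")]),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a contrast battery as TSV
#' @param contrasts A `bb_contrasts`.
#' @param dir Output directory.
#' @export
write_contrasts_tsv <- function(contrasts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("ssr_anova", "ssr_t", "alpha_power_anova",
               "network_anova", "musician_contrast")) {
    df <- contrasts[[nm]]
    if (is.null(df)) next
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
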