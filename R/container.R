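# The package's own plain-text epoch container: one whitespace-delimited
# matrix file per epoch plus a JSON sidecar carrying sample rate, labels
# and condition metadata. Round-trips exactly (full double precision).

#' Write an epoch set as the package container
#'
#' @param epochs List of `bb_epoch`.
#' @param dir Output directory (created if missing); files are named
#'   `epoch_0001.tsv` / `epoch_0001.json` in list order.
#' @export
write_container <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    stem <- file.path(dir, sprintf("epoch_%04d", i))
    utils::write.table(format(e$data, digits = 17), paste0(stem, ".tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    meta <- list(sr = e$sr, condition = e$condition, f_bb = e$f_bb,
                 band = e$band, subject_id = e$subject_id,
                 block_index = e$block_index,
                 channel_labels = rownames(e$data))
    jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Read an epoch set written by [write_container()]
#'
#' @param dir Directory holding `epoch_*.tsv` / `epoch_*.json` pairs.
#' @return List of `bb_epoch`.
#' @export
read_container <- function(dir) {
  tsvs <- sort(list.files(dir, pattern = "^epoch_[0-9]+\\.tsv$",
                          full.names = TRUE))
  if (!length(tsvs)) stop("no epoch files in ", dir)
  lapply(tsvs, function(tsv) {
    meta <- jsonlite::read_json(sub("\\.tsv$", ".json", tsv),
                                simplifyVector = TRUE)
    dat <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE))
    dimnames(dat) <- NULL
    new_epoch(dat, meta$sr, meta$condition,
              f_bb = if (is.null(meta$f_bb)) NA_real_ else meta$f_bb,
              band = if (is.null(meta$band)) NA_character_ else meta$band,
              subject_id = meta$subject_id,
              block_index = meta$block_index,
              channel_labels = meta$channel_labels)
  })
}

#' Default analysis configuration
#'
#' All analysis parameters with their protocol defaults: 256 Hz
#' analysis rate, 0.5 s edge trims, multitaper NW = 4 with a 1024-point
#' FFT, the five EEG/BB bands, the density grid {0.4, 0.6, 0.8}, FDR
#' levels q = 0.05 (global) and q = 0.1 (electrode maps), and both
#' synchrony methods.
#'
#' @return Named list of class `bb_config`.
#' @export
default_config <- function() {
  validate_config(list(
    sr_analysis = 256, trim_s = 0.5, nw = 4, nfft = 1024,
    highpass_hz = 0.5,
    k_density_grid = c(0.4, 0.6, 0.8),
    fdr_q_global = 0.05, fdr_q_local = 0.1,
    methods = c("PLV", "PLI"),
    analysis_band = "alpha",
    seed = 1))
}

#' Load an analysis configuration from YAML
#'
#' Fields omitted from the file keep their [default_config()] values;
#' all fields are validated.
#'
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config())
  for (nm in names(user)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- user[[nm]]
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(cfg$sr_analysis > 0, cfg$trim_s >= 0, cfg$nw > 0,
            cfg$nfft >= 2)
  if (!all(cfg$k_density_grid > 0 & cfg$k_density_grid <= 1)) {
    stop("k_density_grid values must be in (0, 1]")
  }
  if (!all(cfg$methods %in% c("PLV", "PLI"))) {
    stop("methods must be a subset of {PLV, PLI}")
  }
  if (!cfg$analysis_band %in% band_levels) {
    stop("analysis_band must be one of ", paste(band_levels, collapse = ", "))
  }
  stopifnot(cfg$fdr_q_global > 0, cfg$fdr_q_global < 1,
            cfg$fdr_q_local > 0, cfg$fdr_q_local < 1)
  structure(cfg, class = "bb_config")
}

#' @export
print.bb_config <- function(x, ...) {
  cat("<bb_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-14s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
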