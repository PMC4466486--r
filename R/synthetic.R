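#' Configuration of the coupled phase-oscillator generator
#'
#' The synthetic EEG forward model is a network of noisy phase
#' oscillators (Kuramoto-style): channel i's phase advances at
#' `2*pi*center_freq` rad/s, is pulled toward `phase_j - lag[i, j]` with
#' strength `coupling[i, j]`, and diffuses with white phase noise whose
#' intensity sets the oscillators' spectral linewidth (`bandwidth`).
#' Lagged coupling produces synchrony visible to both PLV and PLI;
#' zero-lag synchrony is added separately by instantaneous mixing
#' ([apply_mixing()]), reproducing the volume-conduction confound the
#' phase lag index is designed to reject.
#'
#' @param n_channels Number of channels.
#' @param sr Sample rate, Hz.
#' @param duration_s Epoch duration, seconds.
#' @param center_freq Oscillator frequency, Hz.
#' @param bandwidth Approximate spectral full width of the free-running
#'   oscillator, Hz; converted internally to a phase-diffusion rate.
#' @param coupling n x n matrix of non-negative coupling strengths in
#'   rad/s; must be symmetric with zero diagonal.
#' @param lag n x n matrix of imposed phase lags in radians; must be
#'   antisymmetric.
#' @param seed Integer seed.
#' @return List of class `bb_oscillator_config`.
#' @export
oscillator_config <- function(n_channels = 64, sr = 256, duration_s = 59,
                              center_freq = 10, bandwidth = 2,
                              coupling = NULL, lag = NULL, seed = 1) {
  if (is.null(coupling)) {
    coupling <- matrix(0, n_channels, n_channels)
  }
  if (is.null(lag)) {
    lag <- matrix(0, n_channels, n_channels)
  }
  stopifnot(nrow(coupling) == n_channels, ncol(coupling) == n_channels,
            nrow(lag) == n_channels, ncol(lag) == n_channels)
  if (any(coupling < 0)) stop("coupling strengths must be >= 0")
  if (any(abs(coupling - t(coupling)) > 1e-12)) {
    stop("coupling matrix must be symmetric")
  }
  if (any(abs(diag(coupling)) > 0)) stop("coupling diagonal must be zero")
  if (any(abs(lag + t(lag)) > 1e-12)) stop("lag matrix must be antisymmetric")
  if (sr <= 2 * (center_freq + bandwidth)) {
    stop("sample rate too low for the configured oscillator band")
  }
  structure(list(n_channels = n_channels, sr = sr, duration_s = duration_s,
                 center_freq = center_freq, bandwidth = bandwidth,
                 coupling = coupling, lag = lag, seed = seed),
            class = "bb_oscillator_config")
}

#' Ring coupling matrices for the oscillator network
#'
#' Convenience constructor: couples each channel to its two ring
#' neighbours with equal strength and a fixed phase lag (positive from
#' lower to higher channel index), so the network supports genuinely
#' lagged synchrony that the phase lag index can see.
#'
#' @param n_channels Number of channels.
#' @param strength Coupling strength, rad/s.
#' @param lag_rad Imposed lag in radians between coupled neighbours.
#' @return List with elements `coupling` and `lag`.
#' @export
ring_coupling <- function(n_channels, strength = 15, lag_rad = pi / 4) {
  K <- matrix(0, n_channels, n_channels)
  L <- matrix(0, n_channels, n_channels)
  for (i in seq_len(n_channels - 1)) {
    K[i, i + 1] <- K[i + 1, i] <- strength
    L[i, i + 1] <- lag_rad
    L[i + 1, i] <- -lag_rad
  }
  list(coupling = K, lag = L)
}

#' Simulate coupled noisy phase oscillators
#'
#' Integrates the phase dynamics with the Euler-Maruyama scheme at the
#' configured sample rate and returns both the observable signals
#' (cosine of phase) and the true phases, so downstream synchrony
#' estimates can be validated against ground truth.
#'
#' @param cfg A [oscillator_config()].
#' @return List with `signals` (channels x samples), `phases`
#'   (channels x samples, unwrapped radians), `sr`.
#' @export
generate_coupled_oscillators <- function(cfg) {
  stopifnot(inherits(cfg, "bb_oscillator_config"))
  n <- cfg$n_channels
  steps <- round(cfg$duration_s * cfg$sr)
  dt <- 1 / cfg$sr
  if (max(rowSums(cfg$coupling)) * dt >= 1) {
    warning("coupling so strong that phases can lock within one sample; ",
            "integration may be inaccurate")
  }
  # phase diffusion D = sigma^2/2 gives a Lorentzian line of FWHM D/pi;
  # choose sigma so the free-running linewidth matches `bandwidth`.
  sigma <- sqrt(2 * pi * cfg$bandwidth)
  omega <- rep(2 * pi * cfg$center_freq, n)
  withr_seed(cfg$seed, {
    theta0 <- stats::runif(n, -pi, pi)
    noise <- matrix(stats::rnorm(steps * n, sd = sigma * sqrt(dt)), steps, n)
  })
  theta <- .kuramoto_phases(steps, dt, omega, cfg$coupling, cfg$lag,
                            theta0, noise)
  list(signals = t(cos(theta)), phases = t(theta), sr = cfg$sr)
}

#' 1/f background noise
#'
#' Coloured noise synthesized by spectral shaping of white noise: the
#' amplitude spectrum is multiplied by f^(-exponent/2) so the power
#' spectral density falls off as 1/f^exponent. Output is normalized to
#' unit standard deviation.
#'
#' @param n_samples Number of samples.
#' @param sr Sample rate, Hz.
#' @param exponent Power-law exponent of the PSD (1 = pink noise).
#' @param f_min Frequencies below this are flattened to avoid an
#'   unbounded DC-adjacent amplitude.
#' @return Numeric vector of length `n_samples`.
#' @export
one_over_f_noise <- function(n_samples, sr, exponent = 1, f_min = 0.5) {
  w <- stats::rnorm(n_samples)
  W <- stats::fft(w)
  f <- seq(0, sr - sr / n_samples, length.out = n_samples)
  f[f > sr / 2] <- sr - f[f > sr / 2]      # mirror to physical frequency
  shape <- pmax(f, f_min)^(-exponent / 2)
  shape[1] <- 0                             # remove DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n_samples
  x / stats::sd(x)
}

#' Narrowband Gaussian noise (endogenous rhythm component)
#'
#' White noise shaped by a Gaussian spectral window, used to give every
#' synthetic channel an endogenous alpha rhythm (default 10 +/- 1 Hz) so
#' that the non-binaural normalization baseline has realistic band
#' power. Output has unit standard deviation.
#'
#' @param n_samples Number of samples.
#' @param sr Sample rate, Hz.
#' @param center Center frequency, Hz.
#' @param width Gaussian spectral standard deviation, Hz.
#' @export
narrowband_noise <- function(n_samples, sr, center = 10, width = 0.5) {
  w <- stats::rnorm(n_samples)
  W <- stats::fft(w)
  f <- seq(0, sr - sr / n_samples, length.out = n_samples)
  f[f > sr / 2] <- sr - f[f > sr / 2]
  shape <- exp(-((f - center)^2) / (2 * width^2))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n_samples
  x / stats::sd(x)
}

#' Apply an instantaneous (zero-lag) mixing matrix
#'
#' Emulates volume conduction: each output channel is an instantaneous
#' linear combination of the input channels. Mixing rows must sum to 1
#' so signal scale is preserved; the identity matrix is a no-op.
#'
#' @param signals channels x samples matrix.
#' @param mixing n x n mixing matrix with rows summing to 1.
#' @return Mixed channels x samples matrix.
#' @export
apply_mixing <- function(signals, mixing) {
  stopifnot(is.matrix(signals), is.matrix(mixing),
            nrow(mixing) == ncol(mixing))
  if (nrow(mixing) != nrow(signals)) {
    stop("mixing matrix size ", nrow(mixing),
         " does not match channel count ", nrow(signals))
  }
  if (any(abs(rowSums(mixing) - 1) > 1e-8)) {
    stop("mixing rows must sum to 1")
  }
  mixing %*% signals
}

#' Default volume-conduction mixing
#'
#' Each channel keeps a fraction `1 - spread` of itself and receives
#' `spread` of the instantaneous channel mean — the simplest common
#' source shared by all electrodes.
#'
#' @param n_channels Number of channels.
#' @param spread Fraction of the common component in each channel.
#' @export
default_mixing <- function(n_channels, spread = 0.2) {
  (1 - spread) * diag(n_channels) +
    spread * matrix(1 / n_channels, n_channels, n_channels)
}

#' Effect template for the synthetic dataset
#'
#' Encodes, as free magnitude parameters, the qualitative effects the
#' pipeline is designed to detect: a steady-state entrainment component
#' at the beat frequency during binaural stimulation in `entrain_band`
#' blocks; a cross-band gain of endogenous alpha power during delta-BB
#' blocks; and a change of the musicians' lagged alpha-band coupling
#' (relative, negative = decrease) during binaural theta-/alpha-BB
#' blocks.
#'
#' @param entrain_band EEG band receiving beat-frequency entrainment.
#' @param entrain_amp Amplitude (microvolt) of the entrained sinusoid.
#' @param cross_band_gain Multiplicative gain of endogenous alpha power
#'   during delta-BB binaural segments (1 = none).
#' @param group_pli_delta Relative change of musicians' lagged coupling
#'   strength during binaural theta-/alpha-BB segments, in [-1, Inf)
#'   (0 = none, -0.6 = 60 percent reduction).
#' @param mixing_spread Volume-conduction spread passed to
#'   [default_mixing()].
#' @return List of class `bb_effect_template`.
#' @export
effect_template <- function(entrain_band = "alpha", entrain_amp = 5,
                            cross_band_gain = 1.5, group_pli_delta = -0.6,
                            mixing_spread = 0.2) {
  stopifnot(entrain_band %in% band_levels, entrain_amp >= 0,
            cross_band_gain > 0, group_pli_delta >= -1)
  structure(list(entrain_band = entrain_band, entrain_amp = entrain_amp,
                 cross_band_gain = cross_band_gain,
                 group_pli_delta = group_pli_delta,
                 mixing_spread = mixing_spread),
            class = "bb_effect_template")
}

#' Null effect template (all effect magnitudes zero)
#' @export
null_template <- function() {
  effect_template(entrain_amp = 0, cross_band_gain = 1, group_pli_delta = 0)
}

new_epoch <- function(data, sr, condition, f_bb = NA_real_,
                      band = NA_character_, subject_id = NA_character_,
                      block_index = NA_integer_,
                      channel_labels = NULL) {
  if (is.null(channel_labels)) {
    channel_labels <- default_channel_labels(nrow(data))
  }
  rownames(data) <- channel_labels
  structure(list(data = data, sr = sr, condition = condition,
                 f_bb = f_bb, band = band, subject_id = subject_id,
                 block_index = block_index),
            class = "bb_epoch")
}

#' @export
print.bb_epoch <- function(x, ...) {
  cat(sprintf("<bb_epoch> %s subject=%s block=%s band=%s f_bb=%s | %d ch x %d samples @ %g Hz\n",
              x$condition, x$subject_id, x$block_index, x$band,
              x$f_bb, nrow(x$data), ncol(x$data), x$sr))
  invisible(x)
}

#' Generate all epochs of one synthetic subject
#'
#' For every schedule block, produces one non-binaural (NB) and one
#' binaural (BB) epoch. Both conditions share the same generative
#' background: 1/f noise, an endogenous ~10 Hz alpha rhythm, the
#' coupled-oscillator network, and instantaneous mixing. The BB epoch
#' additionally carries the template's effects (see
#' [effect_template()]).
#'
#' @param subject_id Subject identifier.
#' @param group `"musician"` or `"nonmusician"`.
#' @param schedule A [build_schedule()] table.
#' @param template An [effect_template()].
#' @param seed Integer seed for this subject.
#' @param n_channels,sr,duration_s Epoch geometry.
#' @param noise_1f_amp,alpha_amp,osc_amp Component amplitudes
#'   (microvolt sd).
#' @param osc_strength Baseline lagged coupling strength, rad/s.
#' @param osc_lag Imposed lag between coupled channels, radians.
#' @return List of `bb_epoch` (2 per block: NB then BB).
#' @export
generate_subject_epochs <- function(subject_id, group, schedule, template,
                                    seed, n_channels = 64, sr = 256,
                                    duration_s = 59,
                                    noise_1f_amp = 10, alpha_amp = 5,
                                    osc_amp = 5, osc_strength = 15,
                                    osc_lag = pi / 4) {
  stopifnot(inherits(template, "bb_effect_template"),
            group %in% c("musician", "nonmusician"))
  n_samp <- round(duration_s * sr)
  tgrid <- seq(0, by = 1 / sr, length.out = n_samp)
  mixing <- default_mixing(n_channels, template$mixing_spread)
  ring <- ring_coupling(n_channels, osc_strength, osc_lag)
  epochs <- vector("list", 2L * nrow(schedule))
  withr_seed(seed, {
    for (b in seq_len(nrow(schedule))) {
      blk <- schedule[b, ]
      for (condition in c("NB", "BB")) {
        bb <- condition == "BB"
        alpha_gain <- if (bb && blk$band == "delta") {
          sqrt(template$cross_band_gain)
        } else 1
        k_scale <- if (bb && group == "musician" &&
                       blk$band %in% c("theta", "alpha")) {
          1 + template$group_pli_delta
        } else 1
        cfg <- oscillator_config(
          n_channels = n_channels, sr = sr, duration_s = duration_s,
          coupling = ring$coupling * k_scale, lag = ring$lag,
          seed = sample.int(.Machine$integer.max, 1))
        osc <- generate_coupled_oscillators(cfg)
        bg <- vapply(seq_len(n_channels), function(i) {
          noise_1f_amp * one_over_f_noise(n_samp, sr) +
            alpha_gain * alpha_amp * narrowband_noise(n_samp, sr)
        }, numeric(n_samp))
        x <- t(bg) + osc_amp * osc$signals[, seq_len(n_samp), drop = FALSE]
        if (bb && template$entrain_amp > 0 &&
            blk$band == template$entrain_band) {
          # one deep steady-state source, seen identically (zero lag) by
          # every electrode — the volume-conduction geometry the PLI is
          # built to reject, so entrainment raises band power and PLV
          # without masquerading as lagged coupling
          ent_phase <- stats::runif(1, 0, 2 * pi)
          ent <- template$entrain_amp *
            sin(2 * pi * blk$f_bb * tgrid + ent_phase)
          x <- x + matrix(ent, n_channels, n_samp, byrow = TRUE)
        }
        x <- apply_mixing(x, mixing)
        epochs[[2L * (b - 1L) + (condition == "BB") + 1L]] <- new_epoch(
          x, sr, condition,
          f_bb = if (bb) blk$f_bb else NA_real_,
          band = blk$band, subject_id = subject_id,
          block_index = blk$block_index)
      }
    }
  })
  epochs
}

#' Generate a full synthetic dataset
#'
#' `n_per_group` musicians and `n_per_group` non-musicians, each with
#' one NB and one BB epoch per schedule block. Subjects receive
#' deterministic per-subject seeds derived from `seed`, so the same call
#' is bit-reproducible and individual subjects can be regenerated in
#' isolation by [generate_subject_epochs()].
#'
#' @inheritParams generate_subject_epochs
#' @param n_per_group Subjects per group (>= 2).
#' @param seed Master seed.
#' @param ... Passed on to [generate_subject_epochs()].
#' @return List of class `bb_dataset` with `subjects` (data frame:
#'   `subject_id`, `group`, `seed`), `epochs` (list of `bb_epoch`) and
#'   `ground_truth` (template + generator arguments).
#' @export
generate_dataset <- function(n_per_group, template = effect_template(),
                             schedule = build_schedule(), seed = 1, ...) {
  stopifnot(n_per_group >= 2)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(2 * n_per_group)),
    group = rep(c("musician", "nonmusician"), each = n_per_group),
    stringsAsFactors = FALSE
  )
  subjects$seed <- subject_seeds(seed, nrow(subjects))
  epochs <- list()
  for (s in seq_len(nrow(subjects))) {
    epochs <- c(epochs, generate_subject_epochs(
      subjects$subject_id[s], subjects$group[s], schedule, template,
      seed = subjects$seed[s], ...))
  }
  structure(list(subjects = subjects, epochs = epochs,
                 ground_truth = list(template = template, seed = seed,
                                     args = list(...))),
            class = "bb_dataset")
}

# Deterministic per-subject seeds below 2^31.
subject_seeds <- function(seed, n) {
  (as.numeric(seed) * 2654435761 + 97 * seq_len(n)) %% 2147483647
}

#' @export
print.bb_dataset <- function(x, ...) {
  cat(sprintf("<bb_dataset> %d subjects (%s), %d epochs\n",
              nrow(x$subjects),
              paste(names(table(x$subjects$group)),
                    table(x$subjects$group), collapse = ", ", sep = "="),
              length(x$epochs)))
  invisible(x)
}

#' Assemble a continuous synthetic recording for one subject
#'
#' Concatenates silence, NB and BB segments for the given schedule
#' blocks into one continuous multichannel recording with annotations
#' marking each conditioned segment — the input shape the preprocessing
#' chain expects from a real session.
#'
#' @inheritParams generate_subject_epochs
#' @param blocks Row indices of `schedule` to include (defaults to all).
#' @param segment_s Duration of the NB and BB segments, seconds.
#' @param silence_s Duration of the leading silence per block, seconds.
#' @return A `bb_recording` (see [new_recording()]).
#' @export
generate_recording <- function(subject_id, group, schedule,
                               template = null_template(), seed = 1,
                               n_channels = 8, sr = 256,
                               blocks = seq_len(nrow(schedule)),
                               segment_s = 60, silence_s = 20, ...) {
  sched <- schedule[blocks, , drop = FALSE]
  segs <- list()
  ann <- NULL
  t0 <- 0
  eps <- generate_subject_epochs(subject_id, group, sched, template,
                                 seed = seed, n_channels = n_channels,
                                 sr = sr, duration_s = segment_s, ...)
  for (b in seq_len(nrow(sched))) {
    sil <- matrix(stats::rnorm(n_channels * round(silence_s * sr), sd = 1),
                  n_channels)
    nb <- eps[[2L * b - 1L]]$data
    bb <- eps[[2L * b]]$data
    segs <- c(segs, list(sil, nb, bb))
    ann <- rbind(ann, data.frame(
      onset_s = t0 + c(silence_s, silence_s + segment_s),
      duration_s = segment_s,
      label = sprintf("%s/block%02d", c("NB", "BB"), sched$block_index[b]),
      stringsAsFactors = FALSE))
    t0 <- t0 + silence_s + 2 * segment_s
  }
  new_recording(do.call(cbind, segs), sr,
                channel_labels = default_channel_labels(n_channels),
                annotations = ann)
}
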