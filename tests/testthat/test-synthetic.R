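test_that("generator is bit-reproducible under a fixed seed", {
  sched <- tiny_schedule(c("delta", "alpha"))
  a <- generate_subject_epochs("S01", "musician", sched, effect_template(),
                               seed = 11, n_channels = 4, duration_s = 4)
  b <- generate_subject_epochs("S01", "musician", sched, effect_template(),
                               seed = 11, n_channels = 4, duration_s = 4)
  expect_identical(a, b)
  c <- generate_subject_epochs("S01", "musician", sched, effect_template(),
                               seed = 12, n_channels = 4, duration_s = 4)
  expect_false(identical(a[[1]]$data, c[[1]]$data))
})

test_that("uncoupled oscillators reach only the chance synchrony floor", {
  cf <- oscillator_config(n_channels = 2, duration_s = 59, seed = 21)
  o <- generate_coupled_oscillators(cf)
  ph <- analytic_phase(o$signals, sr = cf$sr)
  phi <- relative_phase(ph$theta[1, ph$valid_mask],
                        ph$theta[2, ph$valid_mask])
  # chance floor for the epoch length: well below locked values
  expect_lt(plv(phi), 0.3)
  expect_lt(pli(phi), 0.3)
})

test_that("strong lagged coupling gives PLV ~ 1 and PLI ~ 1; zero lag is PLI-invisible", {
  K <- matrix(c(0, 80, 80, 0), 2)
  for (lag_val in c(pi / 4, 0)) {
    L <- matrix(c(0, lag_val, -lag_val, 0), 2)
    cf <- oscillator_config(n_channels = 2, duration_s = 30, coupling = K,
                            lag = L, seed = 22)
    o <- generate_coupled_oscillators(cf)
    ph <- analytic_phase(o$signals, sr = cf$sr)
    phi <- relative_phase(ph$theta[1, ph$valid_mask],
                          ph$theta[2, ph$valid_mask])
    expect_gt(plv(phi), 0.9)
    if (lag_val > 0) {
      expect_gt(pli(phi), 0.9)
    } else {
      expect_lt(pli(phi), 0.15)
    }
  }
})

test_that("true oscillator phases match the phases recovered downstream", {
  K <- matrix(c(0, 60, 60, 0), 2)
  L <- matrix(c(0, pi / 3, -pi / 3, 0), 2)
  cf <- oscillator_config(n_channels = 2, duration_s = 30, coupling = K,
                          lag = L, seed = 23)
  o <- generate_coupled_oscillators(cf)
  true_phi <- (o$phases[1, ] - o$phases[2, ]) %% (2 * pi)
  ph <- analytic_phase(o$signals, sr = cf$sr)
  est_phi <- relative_phase(ph$theta[1, ], ph$theta[2, ])[ph$valid_mask]
  expect_equal(plv(est_phi), plv(true_phi[ph$valid_mask]),
               tolerance = 0.05)
})

test_that("oscillator stability warning fires for runaway coupling", {
  K <- matrix(c(0, 500, 500, 0), 2)
  cf <- oscillator_config(n_channels = 2, duration_s = 1, coupling = K,
                          seed = 1)
  expect_warning(generate_coupled_oscillators(cf), "lock within one sample")
})

test_that("instantaneous mixing behaves as specified", {
  set.seed(31)
  x <- matrix(rnorm(3 * 512), 3)
  expect_equal(apply_mixing(x, diag(3)), x)
  expect_equal(nrow(apply_mixing(x, default_mixing(3))), 3)
  bad <- diag(3) * 2
  expect_error(apply_mixing(x, bad), "sum to 1")
  expect_error(apply_mixing(x, diag(4)), "does not match")
})

test_that("zero-lag mixing inflates PLV but leaves PLI at its floor", {
  set.seed(32)
  sr <- 256
  x <- matrix(rnorm(2 * sr * 40), 2)
  mixed <- apply_mixing(x, matrix(c(0.6, 0.4, 0.4, 0.6), 2))
  ph_i <- analytic_phase(bandpass_zerophase(x, "alpha", sr = sr), sr = sr)
  ph_m <- analytic_phase(bandpass_zerophase(mixed, "alpha", sr = sr),
                         sr = sr)
  phi_i <- relative_phase(ph_i$theta[1, ph_i$valid_mask],
                          ph_i$theta[2, ph_i$valid_mask])
  phi_m <- relative_phase(ph_m$theta[1, ph_m$valid_mask],
                          ph_m$theta[2, ph_m$valid_mask])
  expect_gt(plv(phi_m), plv(phi_i) + 0.3)   # PLV strongly elevated
  expect_lt(pli(phi_m), 0.15)               # PLI stays near chance
})

test_that("1/f background has the configured spectral slope", {
  set.seed(33)
  sr <- 256
  x <- matrix(one_over_f_noise(sr * 120, sr, exponent = 1), nrow = 1)
  sp <- multitaper_psd(x, sr = sr)
  sel <- sp$freqs >= 2 & sp$freqs <= 40
  fit <- stats::lm(log10(sp$psd[1, sel]) ~ log10(sp$freqs[sel]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.3)
})

test_that("null dataset leaves normalized power centred on zero dB", {
  sched <- tiny_schedule("alpha")
  ds <- generate_dataset(2, template = null_template(), schedule = sched,
                         seed = 41, n_channels = 4, duration_s = 8)
  pt <- band_power_table(ds)
  expect_lt(abs(mean(pt$value_db)), 1)
})

test_that("one-sample SSR test keeps its nominal type-I rate on null data", {
  # 200 replicate null datasets at reduced size; the rejection rate of
  # the downstream alpha-BB SSR test must stay within the binomial 95%
  # band around alpha = 0.05
  sched <- tiny_schedule("alpha")
  n_rep <- 200
  n_subj <- 6
  rejections <- 0L
  seeds <- 5000 + seq_len(n_rep)
  for (r in seq_len(n_rep)) {
    vals <- numeric(n_subj)
    for (s in seq_len(n_subj)) {
      eps <- generate_subject_epochs(
        sprintf("S%02d", s), "nonmusician", sched, null_template(),
        seed = seeds[r] * 31 + s, n_channels = 2, duration_s = 8,
        osc_strength = 0)
      pt <- band_power_table(list(
        subjects = data.frame(subject_id = sprintf("S%02d", s),
                              group = "nonmusician"),
        epochs = eps))
      vals[s] <- mean(pt$value_db[pt$eeg_band == "alpha"])
    }
    if (one_sample_t(vals, 0)$p < 0.05) rejections <- rejections + 1L
  }
  ci <- stats::qbinom(c(0.025, 0.975), n_rep, 0.05)
  expect_gte(rejections, ci[1])
  expect_lte(rejections, ci[2])
})
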