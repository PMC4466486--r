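test_that("band-pass is zero-phase with the specified pass/stop behaviour", {
  sr <- 256
  t <- seq(0, 20 - 1 / sr, by = 1 / sr)
  trim <- (3 * sr):(length(t) - 3 * sr)
  tone10 <- cos(2 * pi * 10 * t)
  f10 <- bandpass_zerophase(matrix(tone10, 1), "alpha", sr = sr)
  # amplitude within 5%, phase shift zero (max correlation at lag 0)
  expect_equal(stats::sd(f10[1, trim]), stats::sd(tone10[trim]),
               tolerance = 0.05)
  cc <- stats::ccf(f10[1, trim], tone10[trim], lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  tone20 <- cos(2 * pi * 20 * t)
  f20 <- bandpass_zerophase(matrix(tone20, 1), "alpha", sr = sr)
  expect_lt(20 * log10(stats::sd(f20[1, trim]) / stats::sd(tone20[trim])),
            -30)

  # filtering an already narrowband signal is near idempotent
  f10b <- bandpass_zerophase(f10, "alpha", sr = sr)
  expect_equal(f10b[1, trim], f10[1, trim], tolerance = 0.02)

  expect_error(bandpass_zerophase(matrix(tone10, 1), "gamma", sr = 64),
               "Nyquist")
})

test_that("analytic phase has the textbook properties", {
  sr <- 256
  t <- seq(0, 10 - 1 / sr, by = 1 / sr)
  ep_cos <- matrix(cos(2 * pi * 10 * t), 1)
  ph <- analytic_phase(ep_cos, sr = sr)
  expect_true(all(ph$theta > -pi & ph$theta <= pi))
  # unwrapped phase advances at 2*pi*10 rad/s
  th <- ph$theta[1, ph$valid_mask]
  slope <- mean(diff(unwrap_phase(th))) * sr
  expect_equal(slope, 2 * pi * 10, tolerance = 0.01)
  # sin lags cos by pi/2
  ph_sin <- analytic_phase(matrix(sin(2 * pi * 10 * t), 1), sr = sr)
  d <- (ph$theta[1, ph$valid_mask] - ph_sin$theta[1, ph_sin$valid_mask]) %%
    (2 * pi)
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  # positive scaling leaves phase untouched
  ph_scaled <- analytic_phase(3 * ep_cos, sr = sr)
  expect_equal(ph_scaled$theta, ph$theta)
  # edge exclusion: 1 s on each side
  expect_equal(sum(!ph$valid_mask), 2 * sr)
  expect_error(analytic_phase(matrix(0, 1, 100), sr = 10), "all-zero")
})

test_that("relative phase uses the signed wrap convention", {
  th <- c(0.1, 0.2, -0.3)
  expect_equal(relative_phase(th, th), rep(0, 3))
  expect_equal(relative_phase(th + pi / 4, th), rep(pi / 4, 3))
  expect_equal(relative_phase(th - pi / 4, th), rep(7 * pi / 4, 3))
  expect_true(all(relative_phase(runif(50, -10, 10),
                                 runif(50, -10, 10)) >= 0))
  expect_error(relative_phase(1:3, 1:4), "length")
})

test_that("PLV endpoints and chance level match theory", {
  expect_equal(plv(rep(1.234, 100)), 1)
  expect_equal(plv(rep(c(0, pi), 50)), 0)
  # E[PLV] for N independent uniform phases ~ sqrt(pi / (4 N))
  set.seed(81)
  N <- 200
  draws <- vapply(seq_len(1000), function(i) plv(runif(N, 0, 2 * pi)),
                  numeric(1))
  expect_equal(mean(draws), sqrt(pi / (4 * N)), tolerance = 0.05)
  expect_error(plv(1), "at least 2")
})

test_that("PLI endpoints follow the sign-of-sine definition", {
  expect_equal(pli(rep(pi / 2, 10)), 1)
  expect_equal(pli(rep(0, 10)), 0)
  expect_equal(pli(rep(c(pi / 3, -pi / 3), 10)), 0)
  expect_error(pli(0.5), "at least 2")
})

test_that("adjacency matrices are symmetric in [0,1] with zero diagonal", {
  set.seed(82)
  sched <- tiny_schedule("alpha")
  eps <- generate_subject_epochs("S01", "nonmusician", sched,
                                 null_template(), seed = 9,
                                 n_channels = 6, duration_s = 8)
  for (m in c("PLV", "PLI")) {
    adj <- build_adjacency(eps[[1]], "alpha", m)
    a <- adj$a
    expect_equal(a, t(a))
    expect_equal(unname(diag(a)), rep(0, 6))
    expect_true(all(a >= 0 & a <= 1))
  }
  # a duplicated channel is perfectly phase locked with itself
  dup <- eps[[1]]
  dup$data[2, ] <- dup$data[1, ]
  adj_dup <- build_adjacency(dup, "alpha", "PLV")
  expect_equal(unname(adj_dup$a[1, 2]), 1, tolerance = 1e-9)
  # with independent noise, PLI's chance floor sits below PLV's
  adj_plv <- build_adjacency(eps[[1]], "alpha", "PLV")
  adj_pli <- build_adjacency(eps[[1]], "alpha", "PLI")
  off <- upper.tri(adj_plv$a)
  expect_lt(mean(adj_pli$a[off]), mean(adj_plv$a[off]))
  expect_error(build_adjacency(
    bbnet:::new_epoch(matrix(rnorm(100), 1), 256, "NB"), "alpha"),
    "at least 2 channels")
})

test_that("pairwise indices agree with the direct per-pair formulas", {
  set.seed(83)
  th <- matrix(runif(4 * 500, -pi, pi), 4)
  ph <- structure(list(theta = th, valid_mask = rep(TRUE, 500), sr = 100),
                  class = "bb_phase")
  for (m in c("PLV", "PLI")) {
    adj <- adjacency_from_phase(ph, m)
    for (i in 1:3) {
      for (k in (i + 1):4) {
        phi <- relative_phase(th[i, ], th[k, ])
        ref <- if (m == "PLV") plv(phi) else pli(phi)
        expect_equal(unname(adj$a[i, k]), ref, tolerance = 1e-12)
      }
    }
  }
})

test_that("averaging adjacency matrices is the element-wise mean", {
  a1 <- matrix(c(0, .2, .2, 0), 2)
  a2 <- matrix(c(0, .6, .6, 0), 2)
  mk <- function(a) structure(list(a = a, method = "PLV", band = "alpha",
                                   condition = "BB", bb_band = "alpha",
                                   f_bb = 10, subject_id = "S01"),
                              class = "bb_adjacency")
  avg <- average_adjacency(list(mk(a1), mk(a2)))
  expect_equal(avg$a[1, 2], 0.4)
  b <- mk(a2); b$method <- "PLI"
  expect_error(average_adjacency(list(mk(a1), b)), "mixed method")
})
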