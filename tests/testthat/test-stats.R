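test_that("one-sample t handles the degenerate and exemplar cases", {
  expect_equal(one_sample_t(c(-2, -1, 1, 2))$statistic, 0)
  expect_equal(one_sample_t(c(-2, -1, 1, 2))$p, 1)
  set.seed(101)
  r <- one_sample_t(rnorm(32))
  expect_equal(r$df2, 31)
  expect_error(one_sample_t(rep(1, 5)), "zero variance")
})

test_that("one-sample t power matches the noncentral-t closed form", {
  set.seed(102)
  n <- 32; mu <- 0.5; n_rep <- 1000
  rej <- mean(vapply(seq_len(n_rep), function(i) {
    one_sample_t(rnorm(n, mean = mu))$p < 0.05
  }, logical(1)))
  tc <- qt(0.975, n - 1)
  ncp <- mu * sqrt(n)
  power <- 1 - pt(tc, n - 1, ncp) + pt(-tc, n - 1, ncp)
  expect_equal(rej, power, tolerance = 3 * sqrt(power * (1 - power) / n_rep) /
                 power)
})

test_that("paired and unpaired t report the conventional df", {
  set.seed(103)
  x <- rnorm(16); y <- rnorm(16)
  expect_equal(paired_t(x, y)$df2, 15)
  expect_equal(unpaired_t(x, y)$df2, 30)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(unpaired_t(rep(1, 4), rep(2, 4)), "zero variance")
})

test_that("two-sample tests keep their nominal type-I rate", {
  set.seed(104)
  n_rep <- 1000
  rej <- mean(vapply(seq_len(n_rep), function(i) {
    unpaired_t(rnorm(16), rnorm(16))$p < 0.05
  }, logical(1)))
  ci <- qbinom(c(0.025, 0.975), n_rep, 0.05) / n_rep
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("mixed ANOVA reproduces the reference degrees of freedom", {
  d <- expand.grid(subject = sprintf("s%02d", 1:32),
                   beat = c("NB", "BB"),
                   range = c("delta", "theta", "alpha", "beta", "gamma"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 16,
                    "musician", "nonmusician")
  set.seed(105)
  d$value <- rnorm(nrow(d))
  an <- mixed_anova(d, dv = "value", within = c("beat", "range"))
  get <- function(eff) an[an$effect == eff, ]
  expect_equal(get("beat:range")$df1, 4)
  expect_equal(get("beat:range")$df2, 120)
  expect_equal(get("group")$df2, 30)
  expect_equal(get("beat")$df2, 30)
  expect_equal(get("range")$df2, 120)
  expect_equal(nrow(an), 7)
})

test_that("mixed ANOVA F values equal the brute-force SS decomposition", {
  set.seed(106)
  for (r in 1:3) {
    d <- expand.grid(subject = sprintf("s%d", 1:8),
                     w1 = c("a1", "a2"), w2 = c("b1", "b2"),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 4, "g1", "g2")
    d$value <- rnorm(nrow(d)) +
      ifelse(d$group == "g1" & d$w1 == "a1", 0.8, 0)
    an <- mixed_anova(d, dv = "value", within = c("w1", "w2"))
    oracle <- oracle_mixed_anova_F(d)
    for (eff in c("group", "w1", "group:w1", "w2", "group:w2", "w1:w2",
                  "group:w1:w2")) {
      expect_equal(an$statistic[an$effect == eff], oracle[[eff]],
                   tolerance = 1e-8, label = paste("F for", eff))
    }
    # SS identity: parts add to the total
    expect_equal(unname(oracle$ss_check["total"]),
                 unname(oracle$ss_check["parts"]), tolerance = 1e-8)
  }
})

test_that("constant data yields F = 0 across effects by convention", {
  d <- expand.grid(subject = sprintf("s%d", 1:8),
                   w1 = c("a1", "a2"), w2 = c("b1", "b2"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$subject)) <= 4, "g1", "g2")
  d$value <- 5
  an <- mixed_anova(d, dv = "value", within = c("w1", "w2"))
  expect_true(all(an$statistic == 0))
  expect_true(all(an$p == 1))
})

test_that("F equals t^2 for a two-level within factor", {
  set.seed(107)
  d <- expand.grid(subject = sprintf("s%02d", 1:12), beat = c("NB", "BB"),
                   stringsAsFactors = FALSE)
  d$group <- "all"
  d$value <- rnorm(nrow(d)) + ifelse(d$beat == "BB", 0.4, 0)
  # single-group design: drop the between factor by using one level
  an <- mixed_anova(d, dv = "value", between = "group", within = "beat")
  x <- d$value[d$beat == "BB"][order(d$subject[d$beat == "BB"])]
  y <- d$value[d$beat == "NB"][order(d$subject[d$beat == "NB"])]
  tt <- paired_t(x, y)
  expect_equal(an$statistic[an$effect == "beat"], tt$statistic^2,
               tolerance = 1e-8)
})

test_that("mixed ANOVA rejects unbalanced designs", {
  d <- expand.grid(subject = sprintf("s%d", 1:4), w1 = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$group <- "g"
  d$value <- rnorm(nrow(d))
  expect_error(mixed_anova(d[-1, ], dv = "value", within = "w1"),
               "unbalanced")
})

test_that("BH mask reproduces the step-up rule and its properties", {
  r <- fdr_correct(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(r$mask, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(rep(1, 10), 0.05)$mask, rep(FALSE, 10))
  expect_error(fdr_correct(numeric(0)), "empty")
  set.seed(108)
  for (i in 1:50) {
    p <- runif(20)^sample(1:3, 1)
    expect_equal(fdr_correct(p, 0.05)$mask, oracle_bh_mask(p, 0.05))
    # monotone in q
    m1 <- fdr_correct(p, 0.02)$mask
    m2 <- fdr_correct(p, 0.1)$mask
    expect_true(all(m2[m1]))
  }
})

test_that("BH controls the realized false-discovery proportion on nulls", {
  set.seed(109)
  n_rep <- 1000; m <- 64; q <- 0.05
  fdp <- vapply(seq_len(n_rep), function(i) {
    mask <- fdr_correct(runif(m), q)$mask
    if (any(mask)) 1 else 0   # all nulls: any rejection is a false discovery
  }, numeric(1))
  # E[FDP] under the global null equals P(any rejection) <= q
  expect_lte(mean(fdp), q + 2 * sqrt(q * (1 - q) / n_rep))
})

test_that("topography test flags electrodes via FDR", {
  set.seed(110)
  n_s <- 12; n_e <- 16
  x <- matrix(rnorm(n_s * n_e), n_s)
  y <- x + matrix(rnorm(n_s * n_e, sd = 0.3), n_s)
  y[, 1:3] <- y[, 1:3] + 2      # strong effect at three electrodes
  res <- topography_test(y, x, paired = TRUE, q = 0.1)
  expect_true(all(res$significant[1:3]))
  expect_lt(sum(res$significant[-(1:3)]), 3)
  expect_equal(nrow(res), n_e)
})

test_that("rank-sum utility gives a calibrated normal z", {
  set.seed(111)
  r <- mann_whitney(rnorm(16), rnorm(16) + 2)
  expect_lt(r$p, 0.01)
  r0 <- mann_whitney(rnorm(200), rnorm(200))
  expect_gt(r0$p, 0.001)
})
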