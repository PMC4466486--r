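# Independent brute-force oracles used to validate the implemented
# operations. Deliberately written as naive loops so they share no code
# path with the package.

oracle_strength <- function(a) {
  n <- nrow(a)
  s <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i) s[i] <- s[i] + a[i, j]
    }
  }
  s
}

oracle_clustering <- function(a) {
  n <- nrow(a)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(a[i, ] > 0)
    if (k_i < 2) next
    t_i <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          t_i <- t_i + (a[i, j] * a[i, h] * a[j, h])^(1 / 3)
        }
      }
    }
    t_i <- t_i / 2
    c_i[i] <- 2 * t_i / (k_i * (k_i - 1))
  }
  c_i
}

# all-pairs shortest paths on lengths 1/weight by Floyd-Warshall
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && a[i, j] > 0) d[i, j] <- 1 / a[i, j]
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_local_efficiency <- function(a) {
  n <- nrow(a)
  e_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) next
    d <- oracle_distances(a[nb, nb, drop = FALSE])
    vals <- c()
    for (p in seq_along(nb)) {
      for (q in seq_along(nb)) {
        if (p < q) vals <- c(vals, if (is.finite(d[p, q])) 1 / d[p, q] else 0)
      }
    }
    e_i[i] <- mean(vals)
  }
  e_i
}

# random symmetric weighted graph, weights on an optional grid
random_graph <- function(n, p_edge = 0.6, grid = NULL) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p_edge) {
        w <- if (is.null(grid)) stats::runif(1) else sample(grid, 1)
        a[i, j] <- a[j, i] <- w
      }
    }
  }
  a
}

# Benjamini-Hochberg step-up applied literally
oracle_bh_mask <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  thresh <- (seq_len(m) / m) * q
  below <- which(ps <= thresh)
  mask <- logical(m)
  if (length(below)) mask[ord[seq_len(max(below))]] <- TRUE
  mask
}

# full sums-of-squares decomposition of a balanced mixed design
# (one between factor g, within factors w1, w2, subject s nested in g),
# computed from cell means only
oracle_mixed_anova_F <- function(d) {
  gm <- mean(d$value)
  n_s <- length(unique(d$subject))
  lv <- function(f) length(unique(d[[f]]))
  cellmean <- function(...) {
    fs <- c(...)
    stats::aggregate(value ~ ., data = d[, c(fs, "value")], FUN = mean)
  }
  ss <- function(agg, nrep) nrep * sum((agg$value - gm)^2)
  n_g <- lv("group"); n_1 <- lv("w1"); n_2 <- lv("w2")
  reps_per_cell <- nrow(d) / (n_s * n_1 * n_2)
  stopifnot(reps_per_cell == 1)
  ss_g <- ss(cellmean("group"), n_s / n_g * n_1 * n_2)
  ss_s <- ss(cellmean("subject"), n_1 * n_2) - ss_g
  ss_1 <- ss(cellmean("w1"), n_s * n_2)
  ss_g1 <- ss(cellmean("group", "w1"), n_s / n_g * n_2) - ss_g - ss_1
  ss_s1 <- ss(cellmean("subject", "w1"), n_2) - ss_s - ss_g - ss_1 - ss_g1
  ss_2 <- ss(cellmean("w2"), n_s * n_1)
  ss_g2 <- ss(cellmean("group", "w2"), n_s / n_g * n_1) - ss_g - ss_2
  ss_s2 <- ss(cellmean("subject", "w2"), n_1) - ss_s - ss_g - ss_2 - ss_g2
  ss_12 <- ss(cellmean("w1", "w2"), n_s) - ss_1 - ss_2
  ss_g12 <- ss(cellmean("group", "w1", "w2"), n_s / n_g) -
    ss_g - ss_1 - ss_2 - ss_g1 - ss_g2 - ss_12
  ss_tot <- sum((d$value - gm)^2)
  ss_s12 <- ss_tot - ss_g - ss_s - ss_1 - ss_g1 - ss_s1 - ss_2 - ss_g2 -
    ss_s2 - ss_12 - ss_g12
  df_s <- n_s - n_g
  F_of <- function(ss_eff, df_eff, ss_err, df_err) {
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  list(
    group = F_of(ss_g, n_g - 1, ss_s, df_s),
    w1 = F_of(ss_1, n_1 - 1, ss_s1, df_s * (n_1 - 1)),
    `group:w1` = F_of(ss_g1, (n_g - 1) * (n_1 - 1), ss_s1, df_s * (n_1 - 1)),
    w2 = F_of(ss_2, n_2 - 1, ss_s2, df_s * (n_2 - 1)),
    `group:w2` = F_of(ss_g2, (n_g - 1) * (n_2 - 1), ss_s2, df_s * (n_2 - 1)),
    `w1:w2` = F_of(ss_12, (n_1 - 1) * (n_2 - 1), ss_s12,
                   df_s * (n_1 - 1) * (n_2 - 1)),
    `group:w1:w2` = F_of(ss_g12, (n_g - 1) * (n_1 - 1) * (n_2 - 1), ss_s12,
                         df_s * (n_1 - 1) * (n_2 - 1)),
    ss_check = c(total = ss_tot,
                 parts = ss_g + ss_s + ss_1 + ss_g1 + ss_s1 + ss_2 +
                   ss_g2 + ss_s2 + ss_12 + ss_g12 + ss_s12)
  )
}

# small helpers shared by tests
tiny_schedule <- function(bands = c("delta", "theta", "alpha", "beta",
                                    "gamma")) {
  sched <- build_schedule()
  idx <- vapply(bands, function(b) which(sched$band == b)[1], integer(1))
  sched[idx, ]
}

unwrap_phase <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(th[1], d))
}

sine_epoch <- function(freq, duration_s = 8, sr = 256, n_channels = 1,
                       amp = 1, phase = 0) {
  t <- seq(0, duration_s - 1 / sr, by = 1 / sr)
  x <- matrix(rep(amp * cos(2 * pi * freq * t + phase), n_channels),
              nrow = n_channels, byrow = TRUE)
  bbnet:::new_epoch(x, sr, condition = "NB")
}
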