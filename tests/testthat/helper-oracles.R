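# Independent oracles used across the suite.

# Brute-force digamma CMI: O(n^2) loops, no trees, no shared code with the
# package's C++ estimator.  Counts strictly inside the k-th-neighbour radius.
brute_cmi <- function(x, y, z = NULL, k) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  has_z <- !is.null(z) && NCOL(z) > 0
  if (has_z) z <- as.matrix(z)
  supd <- function(a, b) max(abs(a - b))
  total <- 0
  for (i in seq_len(n)) {
    d_full <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      d <- max(supd(x[i, ], x[j, ]), supd(y[i, ], y[j, ]))
      if (has_z) d <- max(d, supd(z[i, ], z[j, ]))
      d
    }, numeric(1))
    eps <- sort(d_full)[k]
    n1 <- n2 <- n3 <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      dz <- if (has_z) supd(z[i, ], z[j, ]) else 0
      if (has_z && dz >= eps) next
      n3 <- n3 + 1L
      if (max(supd(x[i, ], x[j, ]), dz) < eps) n1 <- n1 + 1L
      if (max(supd(y[i, ], y[j, ]), dz) < eps) n2 <- n2 + 1L
    }
    t3 <- if (has_z) digamma(max(n3, 1)) else digamma(n)
    total <- total + t3 - digamma(max(n1, 1)) - digamma(max(n2, 1))
  }
  digamma(k) + total / n
}

# Brute-force enumeration of valid joint-window rows for the equal-rate case
# (0-based start indices; past observation reserved on both series).
brute_joint_rows <- function(n_p, n_q, lam_pq, lam_qp, gamma) {
  rows <- list()
  for (ip in 0:(n_p - 1)) {
    iq <- ip + gamma
    if (ip - 1 < 0) next
    if (iq - 1 < 0) next
    if (ip + lam_pq - 1 > n_p - 1) next
    if (iq + lam_qp - 1 > n_q - 1) next
    rows[[length(rows) + 1L]] <- c(ip = ip, iq = iq)
  }
  rows
}

# small stationary two-series panel with a lagged causal link, for quick
# discovery checks
lagged_pair_panel <- function(n, lag = 1, coef = 0.8, seed = 1) {
  withr::with_seed(seed, {
    x <- as.numeric(arima.sim(list(ar = 0.5), n))
    y <- numeric(n)
    for (t in seq_len(n)[-seq_len(lag)]) {
      y[t] <- 0.4 * y[t - 1] + coef * x[t - lag] + rnorm(1, sd = 0.5)
    }
    ts_panel(tibble::tibble(P = x, Q = y))
  })
}

expect_same_graph <- function(g, edges) {
  ed <- tidy(g)
  got <- sort(paste(ed$from, ed$to, ed$type))
  want <- sort(edges)
  expect_identical(got, want)
}
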