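test_that("window embedding stacks sliding windows", {
  expect_equal(window_embedding(c(1, 2, 3, 4), 2),
               matrix(c(1, 2, 3, 2, 3, 4), nrow = 3))
  expect_equal(window_embedding(c(5, 6, 7), 1), matrix(c(5, 6, 7)))
  expect_equal(nrow(window_embedding(rnorm(20), 4)), 17) # N - lam + 1
  expect_error(window_embedding(rnorm(4), 5), class = "ctmi_invalid_window")
})

test_that("equal-rate alignment matches the brute-force row enumerator", {
  pan <- ts_panel(tibble::tibble(a = rnorm(10), b = rnorm(10)))
  js <- align_joint_sample(pan, "a", "b", 1, 1, gamma_pq = 2)
  expect_equal(js$n, 7)

  withr::with_seed(42, {
    for (case in 1:20) {
      n <- sample(8:20, 1)
      lam_pq <- sample(1:3, 1); lam_qp <- sample(1:3, 1)
      gamma <- sample(-4:4, 1)
      pan <- ts_panel(tibble::tibble(a = rnorm(n), b = rnorm(n)))
      rows <- brute_joint_rows(n, n, lam_pq, lam_qp, gamma)
      if (length(rows) == 0) {
        expect_error(align_joint_sample(pan, "a", "b", lam_pq, lam_qp, gamma),
                     class = "ctmi_empty_sample")
      } else {
        js <- align_joint_sample(pan, "a", "b", lam_pq, lam_qp, gamma)
        expect_equal(js$n, length(rows))
        ip1 <- rows[[1]]["ip"]
        expect_equal(js$x[1, ], pan$a[(ip1 + 1):(ip1 + lam_pq)])
        expect_equal(js$x_past[1, 1], pan$a[ip1]) # one step before the block
      }
    }
  })
})

test_that("identical series at lag zero give identical blocks", {
  v <- rnorm(12)
  pan <- ts_panel(tibble::tibble(a = v, b = v))
  js <- align_joint_sample(pan, "a", "b", 1, 1, 0)
  expect_identical(js$x, js$y)
})

test_that("different sampling rates align on the common tick grid", {
  # rates 2 and 3 per unit: joint rows recur every LCM of the two intervals
  pan <- ts_panel(tibble::tibble(a = c(rnorm(40), rep(NA, 20)),
                                 b = rnorm(60)),
                  rates = c(a = 2, b = 3))
  js <- align_joint_sample(pan, "a", "b", 1, 1, gamma_pq = 0)
  # p observes every 3 ticks, q every 2: common starts every 6 ticks,
  # i.e. consecutive joint rows step by 2 observations of p and 3 of q
  idx_p <- match(js$x[, 1], pan$a)
  idx_q <- match(js$y[, 1], pan$b)
  expect_true(all(diff(idx_p) == 2))
  expect_true(all(diff(idx_q) == 3))
})

test_that("row count is monotone in window sizes and lag magnitude", {
  pan <- ts_panel(tibble::tibble(a = rnorm(30), b = rnorm(30)))
  n_of <- function(lp, lq, g) align_joint_sample(pan, "a", "b", lp, lq, g)$n
  expect_true(n_of(2, 1, 1) <= n_of(1, 1, 1))
  expect_true(n_of(1, 3, 1) <= n_of(1, 1, 1))
  expect_true(n_of(1, 1, 4) <= n_of(1, 1, 1))
  expect_true(n_of(1, 1, -4) <= n_of(1, 1, 0))
})

test_that("alignment is deterministic and drops NA rows", {
  pan <- ts_panel(tibble::tibble(a = rnorm(15), b = rnorm(15)))
  a <- align_joint_sample(pan, "a", "b", 2, 2, 1)
  b <- align_joint_sample(pan, "a", "b", 2, 2, 1)
  expect_identical(a, b)

  v <- rnorm(15); v[8] <- NA
  pan2 <- ts_panel(tibble::tibble(a = v, b = rnorm(15)))
  js <- align_joint_sample(pan2, "a", "b", 1, 1, 0)
  expect_false(anyNA(js$x))
  expect_lt(js$n, align_joint_sample(pan, "a", "b", 1, 1, 0)$n)
})

test_that("panel reader round-trips series and handles a time column", {
  tf <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(time = 1:20, s1 = rnorm(20), s2 = rnorm(20))
  readr::write_csv(df, tf)
  pan <- read_panel(tf)
  expect_setequal(series_names(pan), c("s1", "s2"))
  expect_equal(pan$s1, df$s1)

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(df[-1], tf2)
  expect_equal(unname(n_obs(read_panel(tf2))), c(20L, 20L))
})

test_that("unknown series and invalid panels are rejected", {
  pan <- ts_panel(tibble::tibble(a = rnorm(5), b = rnorm(5)))
  expect_error(align_joint_sample(pan, "a", "zz", 1, 1, 0),
               class = "ctmi_lookup_error")
  expect_error(ts_panel(tibble::tibble(a = 1)), "at least 2")
  expect_error(ts_panel(tibble::tibble(a = rnorm(5)), rates = 1.5),
               "positive integers")
})

test_that("decimation keeps every m-th point and rescales rate metadata", {
  pan <- ts_panel(tibble::tibble(a = as.numeric(1:10), b = as.numeric(1:10)))
  expect_equal(decimate(pan, c(1, 1))$a, pan$a)
  d <- decimate(pan, c(a = 1, b = 2))
  expect_equal(series_length(d$b), 5)
  expect_equal(d$b[1:5], c(1, 3, 5, 7, 9))
  expect_equal(unname(panel_rates(d)), c(2L, 1L))
  expect_error(decimate(pan, 10), "smaller than the series length")
})

test_that("decimation composes multiplicatively on aligned indices", {
  pan <- ts_panel(tibble::tibble(a = rnorm(64), b = rnorm(64)))
  d1 <- decimate(decimate(pan, 2), 3)
  d2 <- decimate(pan, 6)
  expect_equal(d1$a[seq_len(series_length(d2$a))], d2$a[!is.na(d2$a)])
})
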