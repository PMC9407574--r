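test_that("tie-breaking prefers the largest lag then the smallest windows", {
  pan <- ts_panel(tibble::tibble(a = rnorm(40), b = rnorm(40)))
  stub <- function(x, y, z, k) 1 # constant: every grid point ties
  cfg <- estimator_config(k = 2, seed = 1, estimator = stub)
  for (mode in c("greedy", "exhaustive")) {
    r <- ctmi(pan, "a", "b", search_space(3, search = mode), cfg)
    expect_equal(r$gamma_bar, 3L)
    expect_equal(r$lambda_bar_pq, 1L)
    expect_equal(r$lambda_bar_qp, 1L)
  }
})

test_that("fast and generic grid paths agree exactly", {
  pan <- lagged_pair_panel(300, lag = 1, seed = 4)
  cfg_fast <- estimator_config(k = 5, seed = 2)
  cfg_slow <- estimator_config(k = 5, seed = 2,
                               estimator = function(x, y, z, k) {
    ctmi:::cpp_cmi_knn(ctmi:::as_block(x), ctmi:::as_block(y),
                       ctmi:::as_block(z), k)
  })
  a <- ctmi(pan, "P", "Q", search_space(2), cfg_fast)
  b <- ctmi(pan, "P", "Q", search_space(2), cfg_slow)
  expect_identical(a$value, b$value)
  expect_identical(a$gamma_bar, b$gamma_bar)
  ga <- dplyr::arrange(a$grid, gamma, lambda_pq, lambda_qp)
  gb <- dplyr::arrange(b$grid, gamma, lambda_pq, lambda_qp)
  expect_equal(ga$value, gb$value)
})

test_that("the optimal lag recovers a pure shift", {
  withr::with_seed(21, {
    x <- rnorm(2000)
    y <- c(rnorm(2), x[1:1998]) + rnorm(2000, sd = 0.1)
    pan <- ts_panel(tibble::tibble(P = x, Q = y))
  })
  r <- ctmi(pan, "P", "Q", search_space(4), estimator_config(k = 10, seed = 1))
  expect_equal(r$gamma_bar, 2L)
  # symmetry contract: reversed call negates the lag and swaps windows
  r2 <- ctmi(pan, "Q", "P", search_space(4), estimator_config(k = 10,
                                                              seed = 1))
  expect_equal(r2$gamma_bar, -r$gamma_bar)
  expect_identical(r2$value, r$value)
  expect_equal(r2$lambda_bar_pq, r$lambda_bar_qp)
})

test_that("grid search is deterministic under a fixed seed", {
  pan <- lagged_pair_panel(250, seed = 6)
  cfg <- estimator_config(k = 5, seed = 3)
  a <- ctmi(pan, "P", "Q", search_space(2), cfg)
  b <- ctmi(pan, "P", "Q", search_space(2), cfg)
  expect_identical(a$value, b$value)
  expect_identical(a$grid, b$grid)
})

test_that("conditioners in the strict future of both blocks are excluded", {
  pan <- ts_panel(tibble::tibble(a = rnorm(60), b = rnorm(60),
                                 c = rnorm(60)))
  # candidate conditioning lags never go below -gamma_bar
  lags <- ctmi:::cond_candidate_lags(pan, "a", "c", search_space(3),
                                     lower = -2L)
  expect_true(all(lags >= -2L))
  expect_true(all(lags <= 3L))
  cfg <- estimator_config(k = 3, seed = 1, estimator = function(x, y, z, k) 0)
  base <- ctmi(pan, "a", "b", search_space(2), cfg)
  r <- conditional_ctmi(pan, "a", "b", "c", base = base,
                        space = search_space(2), cfg = cfg)
  expect_gte(unname(r$Gamma_bar["c"]), -r$gamma_bar)
})

test_that("an irrelevant conditioner barely changes the measure", {
  withr::with_seed(31, {
    x <- rnorm(800)
    y <- 0.9 * x + rnorm(800, sd = 0.5)
    w <- rnorm(800) # independent of both
    pan <- ts_panel(tibble::tibble(P = x, Q = y, W = w))
  })
  cfg <- estimator_config(k = 10, seed = 5)
  base <- ctmi(pan, "P", "Q", search_space(1), cfg)
  cres <- conditional_ctmi(pan, "P", "Q", "W", base = base,
                           space = search_space(1), cfg = cfg)
  # minimization over placements can only shed estimation noise, not signal
  expect_gt(cres$value, 0.5 * base$value)
})

test_that("independence decisions: power, type-I, and the alpha boundary", {
  pan_dep <- lagged_pair_panel(600, lag = 1, coef = 1, seed = 8)
  d <- independence_decision(pan_dep, "P", "Q", space = search_space(2),
                             cfg = estimator_config(k = 5, B = 50, seed = 2))
  expect_true(d$dependent)

  hits <- withr::with_seed(17, {
    sum(vapply(1:8, function(s) {
      pan0 <- ts_panel(tibble::tibble(P = rnorm(400), Q = rnorm(400)))
      independence_decision(pan0, "P", "Q", space = search_space(2),
                            cfg = estimator_config(k = 5, B = 50,
                                                   seed = s))$dependent
    }, logical(1)))
  })
  expect_lte(hits, 3)

  # alpha = 1 - eps accepts any p-value as dependence
  d1 <- independence_decision(pan_dep, "P", "Q", space = search_space(1),
                              cfg = estimator_config(k = 5, B = 10,
                                                     alpha = 0.999, seed = 1))
  expect_true(d1$dependent)
})

test_that("window growth helps the effect side, not the cause side", {
  # instantaneous cause p -> q: population CMI is flat in the cause window
  # and increasing in the effect window.  Exact covariance of the model
  # p_t = .6 p_{t-1} + e_t^p,  q_t = .6 q_{t-1} + .9 p_t + e_t^q
  # via the linear map from innovations to variables.
  d <- 2; tm <- 30
  phi_q_p <- 0.9
  idx <- function(t, j) t * d + j
  L <- matrix(0, 2 * (tm + 1), 2 * (tm + 1)) # variable index x innovation
  for (t in 1:tm) {
    L[idx(t, 1), ] <- 0.6 * L[idx(t - 1, 1), ]
    L[idx(t, 1), idx(t, 1)] <- 1
    L[idx(t, 2), ] <- 0.6 * L[idx(t - 1, 2), ] + phi_q_p * L[idx(t, 1), ]
    L[idx(t, 2), idx(t, 2)] <- L[idx(t, 2), idx(t, 2)] + 1
  }
  sigma <- L %*% t(L)
  t0 <- 20
  cmi <- function(lp, lq) {
    ix <- vapply(t0:(t0 + lp - 1), idx, numeric(1), j = 1)
    iy <- vapply(t0:(t0 + lq - 1), idx, numeric(1), j = 2)
    iz <- c(idx(t0 - 1, 1), idx(t0 - 1, 2))
    gaussian_cmi(sigma, ix, iy, iz)
  }
  expect_equal(cmi(2, 1), cmi(1, 1), tolerance = 1e-10) # cause window: flat
  expect_gt(cmi(1, 2), cmi(1, 1) + 1e-6) # effect window: strict increase
  expect_gt(cmi(2, 2), cmi(1, 2) - 1e-10) # joint growth never decreases
})

test_that("the example model's conditional zero and oracle optimum hold", {
  m <- example_model(30)
  # instantaneous association vanishes given both one-step pasts
  expect_equal(model_window_cmi(m, 1, 2, 1, 1, gamma = 0), 0,
               tolerance = 1e-9)
  # negative lags carry no information either
  expect_equal(model_window_cmi(m, 1, 2, 1, 1, gamma = -2), 0,
               tolerance = 1e-9)
  # the lag-1 two-window value is (3/2) log 2 in closed form
  expect_equal(model_window_cmi(m, 1, 2, 2, 2, gamma = 1), 1.5 * log(2),
               tolerance = 1e-9)
})
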