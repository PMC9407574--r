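#' Lag and window search space
#'
#' The grid over which the causal temporal mutual information is maximized:
#' lags `gamma` with `|gamma| <= gamma_max` and window sizes
#' `1 <= lambda <= lambda_max`.  By default `lambda_max = gamma_max + 1`;
#' `extended = TRUE` switches to `2 * gamma_max + 1`, which is the window size
#' needed for the skeleton-identifiability argument to cover every lagged
#' dependence, at a substantially higher search cost.
#'
#' @param gamma_max nonnegative integer, maximum lag in time steps.
#' @param lambda_max positive integer, maximum window size.
#' @param extended if `TRUE` and `lambda_max` is not given, use
#'   `2 * gamma_max + 1`.
#' @param search window-selection strategy: `"greedy"` (default) grows the two
#'   windows from size 1 while the estimated measure improves by more than the
#'   estimator noise scale `1/sqrt(n)`, which keeps the reported optimum off
#'   grid points selected purely by estimation noise; `"exhaustive"` takes the
#'   global argmax over the whole grid.
#' @return a `search_space` list with `gamma_max`, `lambda_max`, `search`.
#' @examples
#' search_space(5)
#' @export
search_space <- function(gamma_max = 5L,
                         lambda_max = NULL,
                         extended = FALSE,
                         search = c("greedy", "exhaustive")) {
  gamma_max <- as.integer(gamma_max)
  if (gamma_max < 0L) abort("gamma_max must be nonnegative")
  lambda_max <- as.integer(
    lambda_max %||% (if (extended) 2L * gamma_max + 1L else gamma_max + 1L))
  if (lambda_max < 1L) abort("lambda_max must be positive")
  structure(list(gamma_max = gamma_max, lambda_max = lambda_max,
                 search = match.arg(search)),
            class = "search_space")
}

as_search_space <- function(x) {
  if (inherits(x, "search_space")) x else do.call(search_space, as.list(x))
}

#' Window-based representation of a series
#'
#' Stacks sliding windows of size `lam` into a matrix, one row per window
#' start.  A series of length `N` admits `N - lam + 1` windows.
#'
#' @param series numeric vector.
#' @param lam window size.
#' @param offsets 1-based window start indices; defaults to all of
#'   `1:(N - lam + 1)`.
#' @return numeric matrix with `length(offsets)` rows and `lam` columns.
#' @examples
#' window_embedding(c(1, 2, 3, 4), 2)
#' @export
window_embedding <- function(series, lam, offsets = NULL) {
  n <- length(series)
  lam <- as.integer(lam)
  if (lam < 1L || lam > n) {
    abort("window size must lie in [1, length(series)]",
          class = "ctmi_invalid_window")
  }
  offsets <- offsets %||% seq_len(n - lam + 1L)
  if (length(offsets) && (min(offsets) < 1L || max(offsets) > n - lam + 1L)) {
    abort("offsets out of range", class = "ctmi_invalid_window")
  }
  idx <- outer(as.integer(offsets), 0L:(lam - 1L), `+`)
  matrix(series[idx], nrow = length(offsets), ncol = lam)
}

#' Aligned joint windows of two series
#'
#' Builds the maximal sequence of joint observations pairing windows of `p`
#' (size `lam_pq`) with windows of `q` (size `lam_qp`) whose start times differ
#' by exactly `gamma_pq` sub-unit ticks, together with the one-step past of
#' each series (window of size 1, one observation before each block) and any
#' conditioning blocks.  With equal sampling rates a tick is one time step;
#' with different rates the admissible window starts follow each series' own
#' grid and joint rows recur every least-common-multiple of the two sampling
#' intervals.  Rows touching a missing value are dropped.
#'
#' @param panel a [ts_panel].
#' @param p,q series names.
#' @param lam_pq,lam_qp window sizes for `p` and `q`.
#' @param gamma_pq lag in ticks between the start of `q`'s window and the start
#'   of `p`'s window (positive: `p` leads `q`).
#' @param cond list of conditioning specs, each `list(series =, gamma =,
#'   lam =)`, placing a window of size `lam` starting `gamma` ticks before
#'   `p`'s window start.
#' @return a `joint_sample` list with matrices `x`, `y`, `x_past`, `y_past`,
#'   `cond` (list), row count `n`, and the geometry used.
#' @examples
#' pan <- ts_panel(data.frame(a = rnorm(10), b = rnorm(10)))
#' align_joint_sample(pan, "a", "b", 1, 1, gamma_pq = 2)$n
#' @export
align_joint_sample <- function(panel, p, q, lam_pq, lam_qp, gamma_pq,
                               cond = list()) {
  panel <- as_ts_panel(panel)
  xs <- panel_series(panel, p)
  ys <- panel_series(panel, q)
  lam_pq <- as.integer(lam_pq); lam_qp <- as.integer(lam_qp)
  if (lam_pq > length(xs) || lam_qp > length(ys)) {
    abort("window size exceeds series length", class = "ctmi_invalid_window")
  }
  rates <- panel_rates(panel)
  starts <- panel_starts(panel)
  involved <- unique(c(p, q, vapply(cond, `[[`, character(1), "series")))
  L <- Reduce(lcm_int, rates[involved])
  sp_p <- L %/% rates[[p]]
  sp_q <- L %/% rates[[q]]

  # admissible p-window start indices (0-based), past observation reserved
  ip <- seq_len(max(length(xs) - lam_pq, 0L)) # 0-based starts, past reserved
  tick_p <- starts[[p]] + ip * sp_p
  tick_q <- tick_p + as.integer(gamma_pq)
  iq_num <- tick_q - starts[[q]]
  ok <- iq_num %% sp_q == 0L
  iq <- iq_num %/% sp_q
  ok <- ok & iq >= 1L & (iq + lam_qp - 1L) <= (length(ys) - 1L)
  ip <- ip[ok]; iq <- iq[ok]

  cond_idx <- list()
  for (ci in seq_along(cond)) {
    cs <- cond[[ci]]
    rs <- panel_series(panel, cs$series)
    lam_k <- as.integer(cs$lam %||% 1L)
    sp_r <- L %/% rates[[cs$series]]
    tick_r <- starts[[p]] + ip * sp_p - as.integer(cs$gamma)
    ir_num <- tick_r - starts[[cs$series]]
    ok <- ir_num %% sp_r == 0L
    ir <- ir_num %/% sp_r
    ok <- ok & ir >= 0L & (ir + lam_k - 1L) <= (length(rs) - 1L)
    ip <- ip[ok]; iq <- iq[ok]
    cond_idx <- purrr::map(cond_idx, function(v) v[ok])
    cond_idx[[ci]] <- ir[ok]
  }

  if (length(ip) == 0L) {
    abort("no realizable joint observation", class = "ctmi_empty_sample")
  }

  x <- window_embedding(xs, lam_pq, ip + 1L)
  y <- window_embedding(ys, lam_qp, iq + 1L)
  x_past <- window_embedding(xs, 1L, ip)
  y_past <- window_embedding(ys, 1L, iq)
  zc <- purrr::map2(cond_idx, cond, function(ir, cs) {
    window_embedding(panel_series(panel, cs$series),
                     as.integer(cs$lam %||% 1L), ir + 1L)
  })

  keep <- stats::complete.cases(do.call(cbind, c(list(x, y, x_past, y_past),
                                                 zc)))
  if (!all(keep)) {
    x <- x[keep, , drop = FALSE]; y <- y[keep, , drop = FALSE]
    x_past <- x_past[keep, , drop = FALSE]; y_past <- y_past[keep, , drop = FALSE]
    zc <- purrr::map(zc, function(m) m[keep, , drop = FALSE])
    if (isTRUE(getOption("ctmi.verbose", FALSE))) {
      inform(sprintf("dropped %d joint rows with missing values", sum(!keep)),
             class = "ctmi_na_drop")
    }
  }
  if (nrow(x) == 0L) {
    abort("no realizable joint observation", class = "ctmi_empty_sample")
  }

  structure(list(
    x = x, y = y, x_past = x_past, y_past = y_past, cond = zc,
    n = nrow(x), p = p, q = q, gamma = as.integer(gamma_pq),
    lambdas = c(lam_pq = lam_pq, lam_qp = lam_qp),
    cond_spec = cond
  ), class = "joint_sample")
}

# conditioning block for the estimator: pasts plus any conditioning windows
joint_sample_z <- function(js) {
  do.call(cbind, c(list(js$x_past, js$y_past), js$cond))
}

# candidate lags (in ticks) between two series given their grids
candidate_lags <- function(panel, p, q, space) {
  rates <- panel_rates(panel)
  starts <- panel_starts(panel)
  L <- Reduce(lcm_int, rates[c(p, q)])
  sp_p <- L %/% rates[[p]]
  sp_q <- L %/% rates[[q]]
  g <- gcd_int(sp_p, sp_q)
  lim <- space$gamma_max * max(sp_p, sp_q)
  base <- (starts[[q]] - starts[[p]]) %% g
  lags <- seq.int(-lim, lim)
  lags[lags %% g == base %% g]
}
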