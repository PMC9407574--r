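#' Causal temporal mutual information between two series
#'
#' Maximizes the estimated conditional mutual information between window
#' embeddings of `p` and `q` over all window sizes `1..lambda_max` and lags
#' `|gamma| <= gamma_max`, each grid point conditioning on the one-step past
#' of both series.  Ties are broken by the largest lag, then the smallest `p`
#' window, then the smallest `q` window.  The measure is symmetric:
#' `ctmi(panel, q, p)` has the same value with the lag negated and the windows
#' swapped.
#'
#' @param panel a [ts_panel] (or data frame with one column per series).
#' @param p,q series names.
#' @param space a [search_space].
#' @param cfg an [estimator_config].
#' @return a `ctmi_result`: `value` (nats, floored at 0 for reporting;
#'   `value_raw` keeps the signed estimate), `gamma_bar`, `lambda_bar_pq`,
#'   `lambda_bar_qp`, `n`, the evaluated `grid` tibble, and the optimizing
#'   `sample`.
#' @examples
#' pan <- generate_panel(builtin_structures()$fork, n_time = 200, seed = 1)
#' r <- ctmi(pan$panel, "X1", "X2", search_space(2), estimator_config(k = 5))
#' r$gamma_bar
#' @export
ctmi <- function(panel, p, q, space = search_space(),
                 cfg = estimator_config()) {
  if (identical(p, q)) abort("p and q must be distinct series")
  panel <- prepare_panel(as_ts_panel(panel), seed = jitter_seed(cfg))
  space <- as_search_space(space); cfg <- as_estimator_config(cfg)
  flip <- p > q
  a <- if (flip) q else p
  b <- if (flip) p else q
  res <- ctmi_canonical(panel, a, b, space, cfg)
  if (flip) res <- flip_ctmi(res) else res
}

flip_ctmi <- function(res) {
  out <- res
  out$p <- res$q; out$q <- res$p
  out$gamma_bar <- -res$gamma_bar
  out$lambda_bar_pq <- res$lambda_bar_qp
  out$lambda_bar_qp <- res$lambda_bar_pq
  if (!is.null(res$grid)) {
    out$grid <- dplyr::mutate(res$grid,
      gamma = -.data$gamma,
      lambda_pq = res$grid$lambda_qp, lambda_qp = res$grid$lambda_pq)
  }
  out
}

# exhaustive, deterministic grid search over C(p, q) in canonical order
ctmi_canonical <- function(panel, p, q, space, cfg) {
  lags <- candidate_lags(panel, p, q, space)
  rates <- panel_rates(panel)
  xs <- panel_series(panel, p)
  ys <- panel_series(panel, q)
  fast <- is.null(cfg$estimator) &&
    rates[[p]] == rates[[q]] &&
    panel_starts(panel)[[p]] == panel_starts(panel)[[q]] &&
    length(xs) == length(ys) && !anyNA(xs) && !anyNA(ys)
  grid <- if (fast) {
    tibble::as_tibble(cpp_ctmi_pair_grid(
      xs, ys, as.integer(sort(lags, decreasing = TRUE)),
      space$lambda_max, cfg$k))
  } else {
    ctmi_grid_generic(panel, p, q, lags, space, cfg)
  }
  if (nrow(grid) == 0L) {
    abort("no grid point admits a joint sample larger than k",
          class = "ctmi_estimation_infeasible")
  }
  top <- if (space$search == "exhaustive") {
    dplyr::arrange(grid, dplyr::desc(.data$value), dplyr::desc(.data$gamma),
                   .data$lambda_pq, .data$lambda_qp)[1, ]
  } else {
    greedy_select(grid)
  }
  js <- align_joint_sample(panel, p, q, top$lambda_pq, top$lambda_qp,
                           top$gamma)
  structure(list(
    p = p, q = q,
    value = max(top$value, 0), value_raw = top$value,
    gamma_bar = top$gamma, lambda_bar_pq = top$lambda_pq,
    lambda_bar_qp = top$lambda_qp, n = top$n, sample = js,
    grid = grid), class = "ctmi_result")
}

# full grid by repeated alignment + estimation (different rates, custom
# estimators); the greedy walk then selects on these values, so generic and
# fast paths agree exactly
ctmi_grid_generic <- function(panel, p, q, lags, space, cfg) {
  rows <- list()
  for (gamma in sort(lags, decreasing = TRUE)) {
    for (lam_pq in seq_len(space$lambda_max)) {
      for (lam_qp in seq_len(space$lambda_max)) {
        js <- try_joint_sample(panel, p, q, lam_pq, lam_qp, gamma)
        if (is.null(js) || js$n <= cfg$k) next
        val <- estimate_cmi(js$x, js$y, joint_sample_z(js), cfg)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gamma = gamma, lambda_pq = lam_pq, lambda_qp = lam_qp,
          n = js$n, value = val)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Per-lag stopping points of the window search.  Greedy: start both windows
# at 1 and take the single-window growth step with the larger estimate while
# it strictly improves.  Exhaustive: the slice argmax (smallest windows on
# ties).
slice_optima <- function(grid, search = "greedy") {
  out <- list()
  for (g in sort(unique(grid$gamma), decreasing = TRUE)) {
    slice <- grid[grid$gamma == g, ]
    if (search == "exhaustive") {
      out[[length(out) + 1L]] <-
        dplyr::arrange(slice, dplyr::desc(.data$value), .data$lambda_pq,
                       .data$lambda_qp)[1, ]
      next
    }
    look <- function(lp, lq) {
      row <- slice[slice$lambda_pq == lp & slice$lambda_qp == lq, ]
      if (nrow(row)) row else NULL
    }
    cur <- look(1L, 1L)
    if (is.null(cur)) next
    repeat {
      # a larger window must buy an improvement above the estimator's noise
      # scale ~ 1/sqrt(n); accepting every float-level increase would grow
      # the windows on pure estimation noise
      tau <- 1 / sqrt(cur$n)
      mv_p <- look(cur$lambda_pq + 1L, cur$lambda_qp)
      mv_q <- look(cur$lambda_pq, cur$lambda_qp + 1L)
      step <- NULL
      for (mv in list(mv_p, mv_q)) {
        if (!is.null(mv) && mv$value > cur$value + tau &&
            (is.null(step) || mv$value > step$value)) {
          step <- mv
        }
      }
      if (is.null(step)) break
      cur <- step
    }
    out[[length(out) + 1L]] <- cur
  }
  dplyr::bind_rows(out)
}

greedy_select <- function(grid) {
  tops <- slice_optima(grid, "greedy")
  best <- NULL
  for (i in seq_len(nrow(tops))) {
    cand <- list(value_raw = tops$value[i], gamma_bar = tops$gamma[i],
                 lambda_bar_pq = tops$lambda_pq[i],
                 lambda_bar_qp = tops$lambda_qp[i])
    if (is.null(best) || ctmi_better(cand, best)) best <- cand
  }
  tops[tops$gamma == best$gamma_bar &
         tops$lambda_pq == best$lambda_bar_pq &
         tops$lambda_qp == best$lambda_bar_qp, ][1, ]
}

# tie order: value, then largest gamma, then smallest lambda_pq, lambda_qp
ctmi_better <- function(a, b) {
  if (a$value_raw != b$value_raw) return(a$value_raw > b$value_raw)
  if (a$gamma_bar != b$gamma_bar) return(a$gamma_bar > b$gamma_bar)
  if (a$lambda_bar_pq != b$lambda_bar_pq) {
    return(a$lambda_bar_pq < b$lambda_bar_pq)
  }
  a$lambda_bar_qp < b$lambda_bar_qp
}

try_joint_sample <- function(panel, p, q, lam_pq, lam_qp, gamma,
                             cond = list()) {
  tryCatch(
    align_joint_sample(panel, p, q, lam_pq, lam_qp, gamma, cond = cond),
    ctmi_empty_sample = function(e) NULL,
    ctmi_invalid_window = function(e) NULL)
}

estimate_cmi <- function(x, y, z, cfg) {
  if (!is.null(cfg$estimator)) cfg$estimator(x, y, z, cfg$k)
  else cpp_cmi_knn(as_block(x), as_block(y), as_block(z), cfg$k)
}

jitter_seed <- function(cfg) (as.integer(cfg$seed) + 999983L) %% 2147483647L

#' Conditional causal temporal mutual information
#'
#' Holds the pair geometry (optimal lag and windows) fixed from the
#' unconditional result and minimizes the estimated conditional mutual
#' information over the placement (lag `Gamma_k >= -gamma_bar`, bounded by
#' `gamma_max`) and size (`1..lambda_max`) of one conditioning window per
#' series in `R`, in addition to the one-step pasts.  The search is a
#' coordinate descent over conditioners (others held at lag 0, window 1), two
#' sweeps; ties prefer the largest `Gamma_k`, then the smallest window.
#' Minimizing guarantees that a separating configuration is found if one
#' exists.
#'
#' @inheritParams ctmi
#' @param R character vector of conditioning series (disjoint from `p`, `q`).
#' @param base the unconditional [ctmi()] result for `p`, `q`; computed when
#'   missing.
#' @return a `ctmi_cond_result` with `value`, `value_raw`, per-conditioner
#'   `Gamma_bar` and `lambda_bar`, the inherited pair geometry, `n`, `sample`.
#' @export
conditional_ctmi <- function(panel, p, q, R, base = NULL,
                             space = search_space(),
                             cfg = estimator_config()) {
  if (length(R) == 0L) abort("R must be nonempty; use ctmi() otherwise")
  if (any(R %in% c(p, q))) abort("R must be disjoint from {p, q}")
  panel <- prepare_panel(as_ts_panel(panel), seed = jitter_seed(cfg))
  space <- as_search_space(space); cfg <- as_estimator_config(cfg)
  base <- base %||% ctmi(panel, p, q, space, cfg)
  # work in the orientation with a nonnegative optimal lag
  if (base$gamma_bar < 0) {
    tmp <- p; p <- q; q <- tmp
    base <- flip_ctmi(base)
  }
  gb <- base$gamma_bar
  lam_grid <- seq_len(space$lambda_max)
  state <- purrr::map(R, function(r) list(series = r, gamma = 0L, lam = 1L))
  names(state) <- R

  eval_state <- function(st) {
    js <- try_joint_sample(panel, p, q, base$lambda_bar_pq, base$lambda_bar_qp,
                           gb, cond = unname(st))
    if (is.null(js) || js$n <= cfg$k) return(NULL)
    list(value = estimate_cmi(js$x, js$y, joint_sample_z(js), cfg), js = js)
  }

  best <- eval_state(state)
  if (is.null(best)) {
    abort("no conditioning placement admits a joint sample larger than k",
          class = "ctmi_estimation_infeasible")
  }
  for (sweep in 1:2) {
    for (r in R) {
      gammas <- cond_candidate_lags(panel, p, r, space, lower = -gb)
      for (Gk in sort(gammas, decreasing = TRUE)) {
        for (lk in lam_grid) {
          cand_state <- state
          cand_state[[r]] <- list(series = r, gamma = Gk, lam = lk)
          cand <- eval_state(cand_state)
          if (is.null(cand)) next
          if (cond_better(cand$value, Gk, lk, best$value,
                          state[[r]]$gamma, state[[r]]$lam,
                          tau = 1 / sqrt(best$js$n))) {
            best <- cand
            state <- cand_state
          }
        }
      }
    }
  }
  structure(list(
    p = p, q = q, R = R,
    value = max(best$value, 0), value_raw = best$value,
    gamma_bar = gb,
    lambda_bar_pq = base$lambda_bar_pq, lambda_bar_qp = base$lambda_bar_qp,
    Gamma_bar = purrr::map_int(state, "gamma"),
    lambda_bar = purrr::map_int(state, "lam"),
    n = best$js$n, sample = best$js
  ), class = "ctmi_cond_result")
}

# Minimization order: a placement wins outright when it reduces the value by
# more than the estimator noise scale `tau`; otherwise it wins only without
# worsening the value and with the preferred geometry (larger Gamma, then
# smaller window), so chance fluctuations alone never buy a bigger
# conditioning window.
cond_better <- function(val, G, lam, best_val, best_G, best_lam, tau = 0) {
  if (val < best_val - tau) return(TRUE)
  if (val > best_val) return(FALSE)
  if (G != best_G) return(G > best_G)
  lam < best_lam
}

# realizable conditioning lags for series r relative to p's window starts
cond_candidate_lags <- function(panel, p, r, space, lower) {
  rates <- panel_rates(panel)
  starts <- panel_starts(panel)
  L <- Reduce(lcm_int, rates[c(p, r)])
  sp_p <- L %/% rates[[p]]
  sp_r <- L %/% rates[[r]]
  g <- gcd_int(sp_p, sp_r)
  upper <- space$gamma_max * max(sp_p, sp_r)
  base <- (starts[[p]] - starts[[r]]) %% g
  lags <- seq.int(lower, upper)
  lags[lags %% g == base %% g]
}

#' Decide dependence of two series via CTMI and a permutation test
#'
#' Runs [ctmi()] (or [conditional_ctmi()] when `R` is nonempty), then applies
#' the local permutation test to the optimizing joint sample.  The pair is
#' declared dependent when the p-value does not exceed `cfg$alpha`.
#'
#' @inheritParams conditional_ctmi
#' @param R conditioning series; may be empty.
#' @return list with `dependent`, `p_value` and the measure `result`.
#' @export
independence_decision <- function(panel, p, q, R = character(0),
                                  space = search_space(),
                                  cfg = estimator_config()) {
  panel <- prepare_panel(as_ts_panel(panel), seed = jitter_seed(cfg))
  space <- as_search_space(space); cfg <- as_estimator_config(cfg)
  res <- if (length(R) == 0L) ctmi(panel, p, q, space, cfg)
         else conditional_ctmi(panel, p, q, R, space = space, cfg = cfg)
  p_val <- if (length(R) == 0L) {
    ctmi_max_test(panel, res, space, cfg,
                  seed = pair_seed(cfg$seed, p, q, R))$p_value
  } else {
    test_cfg <- cfg
    test_cfg$seed <- pair_seed(cfg$seed, p, q, R)
    js <- res$sample
    local_permutation_test(js$x, js$y, joint_sample_z(js), test_cfg)$p_value
  }
  list(dependent = p_val <= cfg$alpha, p_value = p_val, result = res)
}

# Selection-aware permutation test of the maximized measure: the observed
# statistic is the maximum of the per-lag window-search endpoints, and each
# permutation replicate is maximized over the same endpoint geometries (its
# own local permutation per lag slice), so the null carries the same
# maximization as the observed value.  Permutations are drawn independently
# across slices, which can only raise the null maximum relative to perfectly
# coupled draws -- the approximation errs conservative.
ctmi_max_test <- function(panel, res, space, cfg, seed = cfg$seed) {
  tops <- slice_optima(res$grid, space$search)
  obs <- max(tops$value)
  stats <- matrix(-Inf, cfg$B, nrow(tops))
  for (i in seq_len(nrow(tops))) {
    js <- try_joint_sample(panel, res$p, res$q, tops$lambda_pq[i],
                           tops$lambda_qp[i], tops$gamma[i])
    if (is.null(js) || js$n <= cfg$k) next
    z <- joint_sample_z(js)
    perms <- withr::with_seed((seed + 17L * i) %% 2147483647, {
      m <- min(cfg$perm_neighborhood, js$n - 1L)
      cpp_local_perms(cpp_knn_indices(as_block(z), m), cfg$B)
    })
    stats[, i] <- if (is.null(cfg$estimator)) {
      cpp_cmi_knn_perms(as_block(js$x), as_block(js$y), as_block(z),
                        cfg$k, perms)
    } else {
      apply(perms, 2L, function(idx) {
        cfg$estimator(js$x[idx, , drop = FALSE], js$y, z, cfg$k)
      })
    }
  }
  null_max <- apply(stats, 1L, max)
  list(p_value = mean(null_max >= obs), statistic = obs,
       null_stats = null_max)
}

# deterministic per-test seed, invariant to the order of p/q and of R
pair_seed <- function(seed, p, q, R = character(0)) {
  toks <- c(sort(c(p, q)), sort(R))
  h <- 0
  for (tok in toks) {
    for (v in utf8ToInt(tok)) h <- (h * 131 + v) %% 1048573
  }
  as.integer((as.numeric(seed) + h * 7919) %% 2147483647)
}

#' @export
print.ctmi_result <- function(x, ...) {
  cat(sprintf(
    "CTMI(%s; %s) = %.4f nats  (gamma = %d, windows = %d/%d, n = %d)\n",
    x$p, x$q, x$value, x$gamma_bar, x$lambda_bar_pq, x$lambda_bar_qp, x$n))
  invisible(x)
}

#' @export
print.ctmi_cond_result <- function(x, ...) {
  cat(sprintf(
    "CTMI(%s; %s | %s) = %.4f nats  (gamma = %d, windows = %d/%d, n = %d)\n",
    x$p, x$q, paste(x$R, collapse = ", "), x$value, x$gamma_bar,
    x$lambda_bar_pq, x$lambda_bar_qp, x$n))
  invisible(x)
}

#' @rdname tidy.summary_graph
#' @export
tidy.ctmi_result <- function(x, ...) x$grid

#' @rdname tidy.summary_graph
#' @export
glance.ctmi_result <- function(x, ...) {
  tibble::tibble(p = x$p, q = x$q, value = x$value,
                 gamma_bar = x$gamma_bar,
                 lambda_bar_pq = x$lambda_bar_pq,
                 lambda_bar_qp = x$lambda_bar_qp, n = x$n)
}
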