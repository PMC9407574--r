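#' Closed-form Gaussian conditional mutual information
#'
#' For jointly Gaussian variables, I(X; Y | Z) has the log-determinant form
#' `(log det S_xz + log det S_yz - log det S_z - log det S_xyz) / 2` (with the
#' `S_z` terms dropped when `iz` is empty).  Used throughout as an independent
#' oracle for the k-NN estimator and for linear-model reasoning about lags and
#' windows.
#'
#' @param sigma covariance matrix.
#' @param ix,iy,iz index vectors into `sigma` for the X, Y and Z variables.
#' @return conditional mutual information in nats.
#' @examples
#' s <- matrix(c(1, .8, .8, 1), 2)
#' gaussian_cmi(s, 1, 2) # -log(1 - .64) / 2
#' @export
gaussian_cmi <- function(sigma, ix, iy, iz = integer(0)) {
  ld <- function(idx) {
    if (length(idx) == 0L) return(0)
    determinant(sigma[idx, idx, drop = FALSE], logarithm = TRUE)$modulus[[1]]
  }
  (ld(c(ix, iz)) + ld(c(iy, iz)) - ld(iz) - ld(c(ix, iy, iz))) / 2
}

#' Exact covariance of a linear lagged structural model
#'
#' For a model `X_t = A_1 X_{t-1} + ... + A_L X_{t-L} + xi_t` started at
#' `X_0 = 0` with independent innovations of unit variance, computes the exact
#' joint covariance of all variables `X_t^j` for `t = 0..t_max` from the
#' moving-average representation.  The model may be nonstationary (e.g.
#' random walks); conditioning on the past inside [gaussian_cmi] then removes
#' the nonstationary component.
#'
#' @param A list of d x d lag coefficient matrices, `A[[l]]` acting at lag `l`.
#' @param t_max last time index.
#' @return a list with `sigma` (covariance, `(t_max + 1) * d` square) and
#'   `index(t, j)` mapping a time/series pair to its row.
#' @examples
#' # bivariate random-walk model with a two-lag cross effect
#' m <- lagged_gaussian_model(
#'   list(matrix(c(1, 1, 0, 1), 2), matrix(c(0, 1, 0, 0), 2)), t_max = 8)
#' gaussian_cmi(m$sigma, m$index(8, 1), m$index(8, 2),
#'              c(m$index(7, 1), m$index(7, 2)))
#' @export
lagged_gaussian_model <- function(A, t_max) {
  d <- nrow(A[[1]])
  L <- length(A)
  # phi[[t]][[s]]: d x d matrix, dX_t / dxi_s (s = 1..t); X_0 = 0
  phi <- vector("list", t_max)
  for (t in seq_len(t_max)) {
    phi[[t]] <- vector("list", t)
    phi[[t]][[t]] <- diag(d)
    for (s in seq_len(t - 1L)) {
      m <- matrix(0, d, d)
      for (l in seq_len(min(L, t - s))) {
        m <- m + A[[l]] %*% phi[[t - l]][[s]]
      }
      phi[[t]][[s]] <- m
    }
  }
  nvar <- (t_max + 1L) * d
  sigma <- matrix(0, nvar, nvar)
  index <- function(t, j) t * d + j
  for (t1 in seq_len(t_max)) for (t2 in seq_len(t_max)) {
    cc <- matrix(0, d, d)
    for (s in seq_len(min(t1, t2))) {
      cc <- cc + phi[[t1]][[s]] %*% t(phi[[t2]][[s]])
    }
    sigma[index(t1, seq_len(d)), index(t2, seq_len(d))] <- cc
  }
  list(sigma = sigma, index = index, d = d, t_max = t_max)
}

#' Gaussian oracle for window-based conditional mutual information
#'
#' Evaluates, in closed form, the conditional mutual information that a CTMI
#' grid point measures on a linear Gaussian lagged model: windows of sizes
#' `lam_pq` and `lam_qp` on series `p` and `q`, offset by `gamma`, conditioned
#' on the one-step past of both series (and optional extra conditioning
#' windows).
#'
#' @param model a [lagged_gaussian_model].
#' @param p,q series indices.
#' @param lam_pq,lam_qp window sizes.
#' @param gamma lag from `p` to `q` in steps.
#' @param t start time of `p`'s window; defaults to a late time point so the
#'   start-up transient has no bearing on the conditional value.
#' @param cond list of `list(series =, gamma =, lam =)` conditioning windows
#'   placed `gamma` steps before `p`'s window start.
#' @return conditional mutual information in nats.
#' @export
model_window_cmi <- function(model, p, q, lam_pq, lam_qp, gamma,
                             t = NULL, cond = list()) {
  t <- t %||% (model$t_max - max(lam_pq, lam_qp, abs(gamma)) -
                 model$t_max %/% 2)
  ix <- vapply(t:(t + lam_pq - 1L), model$index, numeric(1), j = p)
  iy <- vapply((t + gamma):(t + gamma + lam_qp - 1L), model$index,
               numeric(1), j = q)
  iz <- c(model$index(t - 1L, p), model$index(t + gamma - 1L, q))
  for (cs in cond) {
    lam_k <- cs$lam %||% 1L
    iz <- c(iz, vapply((t - cs$gamma):(t - cs$gamma + lam_k - 1L),
                       model$index, numeric(1), j = cs$series))
  }
  gaussian_cmi(model$sigma, ix, iy, iz)
}

#' The two-series worked example model
#'
#' The bivariate benchmark used throughout the documentation and tests: series
#' 1 is a random walk, `X_t^1 = X_{t-1}^1 + xi_t^1`, and series 2 accumulates
#' its own past plus the cause at lags 1 and 2,
#' `X_t^2 = X_{t-1}^2 + X_{t-2}^1 + X_{t-1}^1 + xi_t^2`, with independent
#' unit-variance Gaussian innovations.
#'
#' @param t_max last time index for the exact covariance (see
#'   [lagged_gaussian_model]).
#' @return a [lagged_gaussian_model] for the example.
#' @export
example_model <- function(t_max = 30L) {
  A1 <- matrix(c(1, 1, 0, 1), 2) # X1 -> X1, X1 -> X2 (lag 1), X2 -> X2
  A2 <- matrix(c(0, 1, 0, 0), 2) # X1 -> X2 (lag 2)
  lagged_gaussian_model(list(A1, A2), t_max = t_max)
}

#' Simulate the worked example model
#'
#' @param n length of the simulated series.
#' @param seed RNG seed.
#' @return a [ts_panel] with series `X1`, `X2`.
#' @export
simulate_example_model <- function(n, seed = 1L) {
  withr::with_seed(as.integer(seed %% 2147483647), {
    x1 <- cumsum(rnorm(n))
    x2 <- numeric(n)
    xi2 <- rnorm(n)
    for (t in seq_len(n)[-1]) {
      x2[t] <- x2[t - 1L] + (if (t >= 3L) x1[t - 2L] else 0) + x1[t - 1L] +
        xi2[t]
    }
    ts_panel(tibble::tibble(X1 = x1, X2 = x2))
  })
}

#' Perfect conditional-independence oracle from a causal structure
#'
#' Builds a drop-in replacement for the statistical independence decision used
#' by [pctmi()] and [fcitmi()]: queries are answered by d-separation on the
#' ground-truth summary graph (hidden nodes participate in paths but never in
#' conditioning sets).  The oracle also reports an optimal lag for each pair
#' (the generating lag of a direct edge, or the path sum for a directed path)
#' so that the entropy-reduction orientation rules behave as they would under
#' perfect information.
#'
#' @param spec a [structure_spec] ground truth.
#' @return a function `(p, q, R) -> list(p_value, dependent, value, gamma_bar,
#'   lambda_pq, lambda_qp)` usable as the `ci_test` argument of the discovery
#'   functions.
#' @examples
#' oracle <- dsep_oracle(builtin_structures()$fork)
#' oracle("X2", "X3", "X1")$dependent # FALSE: separated by the common cause
#' @export
dsep_oracle <- function(spec) {
  nodes <- spec$nodes
  edges <- spec$edges
  lag_of <- function(p, q) {
    direct <- edges[edges$from == p & edges$to == q, ]
    if (nrow(direct) > 0L) return(max(direct$gamma))
    d <- path_lag(edges, p, q)
    if (!is.null(d)) d else 0L
  }
  function(p, q, R = character(0)) {
    dep <- !dsep(nodes, edges, p, q, R)
    g <- if (dep) {
      lp <- lag_of(p, q); lq <- lag_of(q, p)
      if (lp > 0L) lp else if (lq > 0L) -lq else 0L
    } else 0L
    list(p_value = if (dep) 0 else 1, dependent = dep,
         value = if (dep) 1 else 0, gamma_bar = as.integer(g),
         lambda_pq = 1L, lambda_qp = 1L)
  }
}

# total lag along a shortest directed path p -> ... -> q, or NULL
path_lag <- function(edges, p, q) {
  dist <- stats::setNames(rep(NA_integer_, 0), character(0))
  frontier <- stats::setNames(0L, p)
  seen <- character(0)
  while (length(frontier)) {
    node <- names(frontier)[1]; acc <- frontier[[1]]
    frontier <- frontier[-1]
    if (node %in% seen) next
    seen <- c(seen, node)
    if (node == q) return(acc)
    out <- edges[edges$from == node, ]
    if (nrow(out)) {
      nxt <- stats::setNames(acc + out$gamma, out$to)
      frontier <- c(frontier, nxt)
    }
  }
  NULL
}

# d-separation of p and q given R in the summary DAG (reachability form)
dsep <- function(nodes, edges, p, q, R) {
  parents <- function(v) edges$from[edges$to == v]
  children <- function(v) edges$to[edges$from == v]
  has_desc_in_R <- function(v) {
    seen <- character(0); stack <- v
    while (length(stack)) {
      cur <- stack[[1]]; stack <- stack[-1]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      if (cur %in% R) return(TRUE)
      stack <- c(stack, children(cur))
    }
    FALSE
  }
  # Bayes-ball: states are (node, direction), direction "up" = arrived from a
  # child (moving against arrows), "down" = arrived from a parent
  visited <- character(0)
  queue <- list(c(p, "up"))
  while (length(queue)) {
    st <- queue[[1]]; queue <- queue[-1]
    key <- paste(st, collapse = "|")
    if (key %in% visited) next
    visited <- c(visited, key)
    node <- st[[1]]; dir <- st[[2]]
    if (node == q && node != p) return(FALSE)
    in_R <- node %in% R
    if (dir == "up" && !in_R) {
      for (pa in parents(node)) queue <- c(queue, list(c(pa, "up")))
      for (ch in children(node)) queue <- c(queue, list(c(ch, "down")))
    } else if (dir == "down") {
      if (!in_R) {
        for (ch in children(node)) queue <- c(queue, list(c(ch, "down")))
      }
      if (in_R || has_desc_in_R(node)) {
        for (pa in parents(node)) queue <- c(queue, list(c(pa, "up")))
      }
    }
  }
  TRUE
}
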