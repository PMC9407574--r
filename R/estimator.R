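#' Estimator and test configuration
#'
#' Settings shared by the k-nearest-neighbour conditional mutual information
#' estimator and the local permutation test.
#'
#' @param k positive integer, number of nearest neighbours (must stay below
#'   every sample size it is applied to).
#' @param B positive integer, number of permutation replicates.
#' @param alpha significance level in (0, 1).
#' @param seed integer seed from which all randomness (jitter, permutations)
#'   is derived.
#' @param perm_neighborhood size of the conditioning-space neighbourhood the
#'   local permutation draws from.
#' @param estimator optional replacement estimator `function(x, y, z, k)`
#'   returning a numeric value; used for testing the surrounding machinery.
#' @return an `estimator_config` list.
#' @examples
#' estimator_config(k = 10, B = 100)
#' @export
estimator_config <- function(k = 10L, B = 100L, alpha = 0.05, seed = 1L,
                             perm_neighborhood = 5L, estimator = NULL) {
  k <- as.integer(k); B <- as.integer(B)
  if (k < 1L) abort("k must be positive")
  if (B < 1L) abort("B must be positive")
  if (!(alpha > 0 && alpha < 1)) abort("alpha must lie in (0, 1)")
  structure(list(k = k, B = B, alpha = alpha, seed = as.integer(seed),
                 perm_neighborhood = as.integer(perm_neighborhood),
                 estimator = estimator),
            class = "estimator_config")
}

as_estimator_config <- function(x) {
  if (inherits(x, "estimator_config")) x else do.call(estimator_config, as.list(x))
}

#' Supremum distance between two points
#'
#' The maximum absolute coordinate-wise difference, the metric under which all
#' neighbour counts of the estimator are taken.
#'
#' @param u,v numeric vectors of equal length.
#' @return nonnegative scalar.
#' @examples
#' sup_distance(c(1, 4), c(2, 2))
#' @export
sup_distance <- function(u, v) {
  if (length(u) != length(v)) {
    abort("u and v must have the same dimension", class = "ctmi_shape_error")
  }
  max(abs(u - v))
}

#' k-nearest-neighbour conditional mutual information
#'
#' Digamma estimator of I(X; Y | Z) under the supremum distance: with
#' `eps_i` the distance from joint point i to its k-th neighbour in the full
#' (X, Y, Z) space, and `n1`, `n2`, `n3` the numbers of points strictly closer
#' than `eps_i` in the (X, Z), (Y, Z) and (Z) subspaces, the estimate is
#' `psi(k) + mean(psi(n3) - psi(n1) - psi(n2))`.  With an empty `z` the
#' construction reduces to the classical k-NN mutual information estimator,
#' `psi(n)` replacing the `psi(n3)` term.  Values are in nats and may be
#' slightly negative through estimation error.  The formula is exactly
#' symmetric in `x` and `y`.
#'
#' @param x,y numeric matrices (or vectors) with one row per observation.
#' @param z optional conditioning matrix; `NULL` or zero columns for none.
#' @param k number of neighbours; must satisfy `k < n`.
#' @return a `cmi_estimate` list with `value`, `n`, `k`.
#' @examples
#' x <- rnorm(300); y <- rnorm(300)
#' knn_cmi(x, y, k = 5)$value # near 0 for independent series
#' @export
knn_cmi <- function(x, y, z = NULL, k = 10L) {
  x <- as_block(x); y <- as_block(y)
  z <- if (is.null(z)) matrix(numeric(0), nrow(x), 0L) else as_block(z)
  n <- nrow(x)
  if (nrow(y) != n || (ncol(z) > 0L && nrow(z) != n)) {
    abort("blocks must be row-aligned", class = "ctmi_shape_error")
  }
  k <- as.integer(k)
  if (n <= k) {
    abort("sample size must exceed k", class = "ctmi_sample_size_error")
  }
  value <- cpp_cmi_knn(x, y, z, k)
  structure(list(value = value, n = n, k = k), class = "cmi_estimate")
}

as_block <- function(x) {
  if (is.matrix(x)) storage.mode(x) <- "double" else x <- matrix(as.double(x))
  x
}

#' Local permutation test of conditional independence
#'
#' Permutation p-value for the null X independent of Y given Z: rows of `x`
#' are permuted within neighbourhoods of similar `z` values (sup-distance
#' nearest neighbours, drawn without replacement as far as possible) so that
#' the permuted samples respect the conditional structure; with empty `z` the
#' permutation is unrestricted.  The p-value is the fraction of permutation
#' replicates whose estimate reaches the observed one, hence always a multiple
#' of `1 / B`.
#'
#' @inheritParams knn_cmi
#' @param cfg an [estimator_config]; `cfg$seed` makes the test reproducible.
#' @return list with `p_value`, `statistic` (observed estimate), `n`, and the
#'   vector of permutation statistics.
#' @export
local_permutation_test <- function(x, y, z = NULL, cfg = estimator_config()) {
  cfg <- as_estimator_config(cfg)
  x <- as_block(x); y <- as_block(y)
  z <- if (is.null(z)) matrix(numeric(0), nrow(x), 0L) else as_block(z)
  n <- nrow(x)
  if (n <= cfg$k) {
    abort("sample size must exceed k", class = "ctmi_sample_size_error")
  }
  est <- function(xx) {
    if (is.null(cfg$estimator)) cpp_cmi_knn(xx, y, z, cfg$k)
    else cfg$estimator(xx, y, z, cfg$k)
  }
  observed <- est(x)
  perms <- withr::with_seed(cfg$seed %% 2147483647, {
    if (ncol(z) == 0L) {
      matrix(replicate(cfg$B, sample.int(n)), nrow = n)
    } else {
      m <- min(cfg$perm_neighborhood, n - 1L)
      cpp_local_perms(cpp_knn_indices(z, m), cfg$B)
    }
  })
  stats <- if (is.null(cfg$estimator)) {
    cpp_cmi_knn_perms(x, y, z, cfg$k, perms)
  } else {
    apply(perms, 2L, function(idx) cfg$estimator(x[idx, , drop = FALSE], y, z,
                                                 cfg$k))
  }
  p <- mean(stats >= observed)
  list(p_value = p, statistic = observed, n = n, permutation_stats = stats)
}
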