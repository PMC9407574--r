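#' Ground-truth structure specification
#'
#' Describes the causal structure a synthetic panel is generated from: lagged
#' directed edges between series, optionally hidden series (simulated, then
#' dropped from the output), and the coefficient/noise law of the
#' structural-equation process.  Defaults follow the benchmark protocol used
#' throughout the package: coefficients uniform on
#' `[-coef_high, -coef_low] U [coef_low, coef_high]`, one nonlinearity per
#' edge drawn from absolute value / tanh / sine / cosine, innovations
#' `noise_scale * N(0, noise_var)`, and a linear lag-1 self-loop on every
#' series.
#'
#' @param nodes character vector of series names.
#' @param edges data frame with columns `from`, `to` and optionally `gamma`
#'   (lag, default 1).
#' @param hidden subset of `nodes` withheld from the output panel.
#' @param noise_scale multiplier on the innovations.
#' @param noise_var variance of the Gaussian innovations.
#' @param coef_low,coef_high coefficient magnitude bounds.
#' @param nonlinearities candidate link functions for cause terms.
#' @return a `structure_spec`.
#' @examples
#' structure_spec(c("A", "B"), data.frame(from = "A", to = "B", gamma = 2))
#' @export
structure_spec <- function(nodes, edges, hidden = character(0),
                           noise_scale = 0.1, noise_var = 15,
                           coef_low = 0.1, coef_high = 1,
                           nonlinearities = c("abs", "tanh", "sin", "cos")) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) && !"gamma" %in% names(edges)) edges$gamma <- 1L
  if (nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(0), to = character(0),
                            gamma = integer(0))
  }
  edges$gamma <- as.integer(edges$gamma)
  stopifnot(all(edges$from %in% nodes), all(edges$to %in% nodes),
            all(edges$gamma >= 0L), all(hidden %in% nodes))
  if (any(edges$from == edges$to)) {
    abort("self-loops are implicit; edges must join distinct nodes")
  }
  ig <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                      vertices = data.frame(name = nodes))
  if (!igraph::is_dag(ig)) abort("summary structure must be acyclic")
  structure(list(nodes = nodes, edges = edges, hidden = hidden,
                 noise_scale = noise_scale, noise_var = noise_var,
                 coef_low = coef_low, coef_high = coef_high,
                 nonlinearities = nonlinearities),
            class = "structure_spec")
}

#' Benchmark structures
#'
#' The named causal structures used by the simulation benchmark: `fork` (one
#' common cause of two effects), `v_structure` (two independent causes of one
#' effect), `diamond` (a four-node double path), and `seven_hidden`, a
#' synthetic seven-series template with two hidden common causes, each
#' confounding a pair of observed series (latent regime; the exact published
#' topology of that regime is not recoverable, so this template is a
#' reconstruction).  All inter-series edges use lag 1.
#'
#' @return named list of [structure_spec]s.
#' @examples
#' names(builtin_structures())
#' @export
builtin_structures <- function() {
  list(
    fork = structure_spec(
      c("X1", "X2", "X3"),
      tibble::tibble(from = c("X1", "X1"), to = c("X2", "X3"))),
    v_structure = structure_spec(
      c("X1", "X2", "X3"),
      tibble::tibble(from = c("X1", "X2"), to = c("X3", "X3"))),
    diamond = structure_spec(
      c("X1", "X2", "X3", "X4"),
      tibble::tibble(from = c("X1", "X1", "X2", "X3"),
                     to = c("X2", "X3", "X4", "X4"))),
    seven_hidden = structure_spec(
      paste0("X", 1:9),
      tibble::tibble(
        from = c("X1", "X2", "X3", "X5", "X8", "X8", "X9", "X9"),
        to = c("X2", "X3", "X4", "X6", "X1", "X5", "X6", "X7")),
      hidden = c("X8", "X9"))
  )
}

#' Simulate a panel from a causal structure
#'
#' Structural-equation generator: every series follows
#' `X_t = a_self * X_{t-1} + sum_parents a_pq * f(X_{t-gamma}^parent) +
#' noise_scale * xi_t` with `xi_t ~ N(0, noise_var)`, `X_0 = 0`, coefficients
#' drawn once per edge uniformly from the two-sided magnitude band, and one
#' nonlinearity `f` per edge drawn uniformly from the candidate set.  Hidden
#' series are simulated and then dropped.  Trajectories exceeding 1e12 in
#' absolute value trigger a fresh coefficient draw (logged); `burn_in`
#' observations can be discarded from the front.
#'
#' @param spec a [structure_spec].
#' @param n_time number of retained observations per series.
#' @param seed RNG seed.
#' @param burn_in observations simulated and discarded before the panel
#'   starts (default 0: the series are used from their zero start).
#' @return list with `panel` (a [ts_panel] of the observed series) and
#'   `truth` (the observed-node [summary_graph]; children of a common hidden
#'   cause are joined by a bidirected edge).
#' @examples
#' sim <- generate_panel(builtin_structures()$fork, n_time = 300, seed = 7)
#' glance(sim$truth)
#' @export
generate_panel <- function(spec, n_time, seed = 1L, burn_in = 0L) {
  stopifnot(inherits(spec, "structure_spec"), n_time >= 10L)
  if (nrow(spec$edges) && max(spec$edges$gamma) >= n_time) {
    abort("lags must be smaller than the series length")
  }
  total <- n_time + burn_in
  withr::with_seed(as.integer(seed %% 2147483647), {
    for (attempt in 1:20) {
      X <- simulate_structural(spec, total)
      if (max(abs(X)) <= 1e12) break
      if (isTRUE(getOption("ctmi.verbose", FALSE))) {
        inform("explosive trajectory; redrawing coefficients",
               class = "ctmi_regenerate")
      }
    }
  })
  if (max(abs(X)) > 1e12) {
    abort("generator failed to produce a stable trajectory")
  }
  observed <- setdiff(spec$nodes, spec$hidden)
  panel <- ts_panel(tibble::as_tibble(X)[
    seq.int(burn_in + 1L, total), observed, drop = FALSE])
  list(panel = panel, truth = truth_graph(spec))
}

simulate_structural <- function(spec, total) {
  d <- length(spec$nodes)
  nl_funs <- list(abs = abs, tanh = tanh, sin = sin, cos = cos)
  draw_coef <- function(m) {
    sample(c(-1, 1), m, replace = TRUE) *
      runif(m, spec$coef_low, spec$coef_high)
  }
  a_self <- stats::setNames(draw_coef(d), spec$nodes)
  ne <- nrow(spec$edges)
  a_edge <- draw_coef(ne)
  f_edge <- sample(spec$nonlinearities, ne, replace = TRUE)
  X <- matrix(0, total, d, dimnames = list(NULL, spec$nodes))
  noise <- matrix(rnorm(total * d, 0, sqrt(spec$noise_var)), total, d) *
    spec$noise_scale
  for (t in 2:total) {
    for (j in seq_len(d)) {
      v <- a_self[[j]] * X[t - 1L, j]
      X[t, j] <- v
    }
    if (ne) {
      for (e in seq_len(ne)) {
        lag <- max(spec$edges$gamma[e], 1L) # instantaneous handled below
        if (spec$edges$gamma[e] == 0L) next
        if (t - lag >= 1L) {
          X[t, spec$edges$to[e]] <- X[t, spec$edges$to[e]] +
            a_edge[e] * nl_funs[[f_edge[e]]](X[t - lag, spec$edges$from[e]])
        }
      }
    }
    X[t, ] <- X[t, ] + noise[t, ]
    if (ne && any(spec$edges$gamma == 0L)) {
      # instantaneous effects are added after noise, in topological order
      ord <- topo_order(spec)
      for (j in ord) {
        for (e in which(spec$edges$to == j & spec$edges$gamma == 0L)) {
          X[t, j] <- X[t, j] +
            a_edge[e] * nl_funs[[f_edge[e]]](X[t, spec$edges$from[e]])
        }
      }
    }
  }
  X
}

topo_order <- function(spec) {
  ig <- igraph::graph_from_data_frame(
    spec$edges[, c("from", "to")], vertices = data.frame(name = spec$nodes))
  names(igraph::topo_sort(ig))
}

# ground-truth summary graph over the observed nodes
truth_graph <- function(spec) {
  observed <- setdiff(spec$nodes, spec$hidden)
  mode <- if (length(spec$hidden)) "pag" else "cpdag"
  g <- summary_graph(observed, mode = mode)
  ed <- spec$edges[spec$edges$from %in% observed & spec$edges$to %in% observed,
                   , drop = FALSE]
  for (i in seq_len(nrow(ed))) {
    g <- sg_add_edge(g, ed$from[i], ed$to[i], MARK_TAIL, MARK_ARROW)
  }
  for (h in spec$hidden) {
    kids <- intersect(spec$edges$to[spec$edges$from == h], observed)
    if (length(kids) >= 2L) {
      cmb <- utils::combn(kids, 2L)
      for (i in seq_len(ncol(cmb))) {
        if (!sg_has_edge(g, cmb[1, i], cmb[2, i])) {
          g <- sg_add_edge(g, cmb[1, i], cmb[2, i], MARK_ARROW, MARK_ARROW)
        }
      }
    }
  }
  g
}

#' Directed-edge F1 score of an inferred summary graph
#'
#' Compares predicted against true directed inter-series edges, ignoring
#' self-loops.  A predicted edge counts as a true positive when it carries an
#' arrowhead at the same effect end as a true edge (a tail-to-arrow edge, or a
#' circle-to-arrow edge in a partial ancestral graph); bidirected edges match
#' true bidirected (confounded) pairs.  Undirected or fully undetermined
#' predicted edges never count as recovered.  When neither graph has any
#' inter-series edge the score is 1.
#'
#' @param pred,truth [summary_graph]s over the same node set.
#' @return F1 in `[0, 1]`.
#' @examples
#' tr <- generate_panel(builtin_structures()$fork, 100, seed = 1)$truth
#' f1_directed(tr, tr)
#' @export
f1_directed <- function(pred, truth) {
  if (!setequal(pred$nodes, truth$nodes)) {
    abort("graphs must share the same node set")
  }
  classify <- function(g) {
    ed <- tidy(g)
    dir <- ed[ed$type == "directed" |
                (ed$mark_to == "arrow" & ed$mark_from == "circle"), ]
    list(
      directed = if (nrow(dir)) paste(dir$from, dir$to, sep = ">")
                 else character(0),
      bidirected = {
        bi <- ed[ed$type == "bidirected", ]
        if (nrow(bi)) {
          purrr::map2_chr(bi$from, bi$to,
                          function(a, b) paste(sort(c(a, b)), collapse = "<>"))
        } else character(0)
      })
  }
  p <- classify(pred); t <- classify(truth)
  tp <- length(intersect(p$directed, t$directed)) +
    length(intersect(p$bidirected, t$bidirected))
  fp <- length(setdiff(p$directed, t$directed)) +
    length(setdiff(p$bidirected, t$bidirected))
  fn <- length(setdiff(t$directed, p$directed)) +
    length(setdiff(t$bidirected, p$bidirected))
  if (tp + fp + fn == 0L) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Run the simulation benchmark
#'
#' Generates replicate panels from named benchmark structures, runs [pctmi()]
#' (or [fcitmi()] when the structure has hidden nodes, or when `latent =
#' TRUE`), and scores each run with [f1_directed()].
#'
#' @param structures character vector naming entries of
#'   [builtin_structures()], or a named list of [structure_spec]s.
#' @param replicates independent datasets per structure.
#' @param n_time series length.
#' @param space a [search_space].
#' @param cfg an [estimator_config]; `cfg$seed` drives the whole benchmark.
#'   The benchmark default uses 50 permutation replicates per test: decisions
#'   at the 0.05 level only need that resolution, and it halves the run time
#'   of a full sweep.
#' @param latent force the latent-variable learner; default: decided per
#'   structure by the presence of hidden nodes.
#' @param ci_test optional oracle test, passed through to the learners.
#' @return a `ctmi_benchmark` tibble with one row per replicate (`structure`,
#'   `replicate`, `f1`, `seconds`, `error`); `glance()` summarizes mean and
#'   standard deviation per structure.
#' @examples
#' b <- run_benchmark("fork", replicates = 2, n_time = 100,
#'                    ci_test = dsep_oracle(builtin_structures()$fork))
#' glance(b)
#' @export
run_benchmark <- function(structures = c("fork", "v_structure", "diamond"),
                          replicates = 10L, n_time = 1000L,
                          space = search_space(5L),
                          cfg = estimator_config(B = 50L),
                          latent = NULL, ci_test = NULL) {
  specs <- if (is.character(structures)) {
    builtin_structures()[structures]
  } else {
    structures
  }
  if (any(vapply(specs, is.null, logical(1)))) {
    abort("unknown structure name")
  }
  cfg <- as_estimator_config(cfg)
  rows <- purrr::imap(specs, function(spec, name) {
    purrr::map(seq_len(replicates), function(r) {
      rep_seed <- (as.numeric(cfg$seed) * 1009 + r * 9973) %% 2147483647
      sim <- generate_panel(spec, n_time = n_time, seed = rep_seed)
      use_latent <- latent %||% (length(spec$hidden) > 0L)
      rep_cfg <- cfg
      rep_cfg$seed <- as.integer(rep_seed)
      t0 <- proc.time()[["elapsed"]]
      out <- tryCatch({
        g <- if (use_latent) {
          fcitmi(sim$panel, space, rep_cfg, ci_test = ci_test)
        } else {
          pctmi(sim$panel, space, rep_cfg, ci_test = ci_test)
        }
        list(f1 = f1_directed(g, sim$truth), error = NA_character_)
      }, error = function(e) list(f1 = NA_real_,
                                  error = conditionMessage(e)))
      tibble::tibble(structure = name, replicate = r, f1 = out$f1,
                     seconds = proc.time()[["elapsed"]] - t0,
                     error = out$error)
    })
  })
  out <- dplyr::bind_rows(purrr::list_flatten(rows))
  class(out) <- c("ctmi_benchmark", class(out))
  out
}

#' @rdname tidy.summary_graph
#' @export
glance.ctmi_benchmark <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$structure),
    replicates = dplyr::n(),
    mean_f1 = mean(.data$f1, na.rm = TRUE),
    sd_f1 = if (dplyr::n() > 1L) stats::sd(.data$f1, na.rm = TRUE) else 0,
    failed = sum(!is.na(.data$error)),
    .groups = "drop")
}

#' Plot benchmark scores
#'
#' One point per replicate and a mean bar per structure.
#'
#' @param object a `ctmi_benchmark` tibble from [run_benchmark()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ctmi_benchmark <- function(object, ...) {
  sm <- glance(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$structure, y = .data$f1)) +
    ggplot2::geom_col(data = sm,
                      ggplot2::aes(y = .data$mean_f1), width = 0.6,
                      fill = "grey80") +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "directed-edge F1") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
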