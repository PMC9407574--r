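#' Skeleton of the summary causal graph
#'
#' PC-stable-style edge removal driven by CTMI: starting from the complete
#' graph over the series, conditioning sets of growing cardinality `n` are
#' enumerated from the current adjacencies (subject to the lag-admissibility
#' filter: a conditioner must not lie strictly in the future of both endpoint
#' series, judged from the cached pairwise optimal lags).  All candidate tests
#' of one cardinality are scored by their (conditional) CTMI value, sorted
#' ascending, and popped: a test whose edge and conditioning set are still
#' present is run through the local permutation test, and the edge is removed
#' (recording the separating set) when the p-value exceeds `cfg$alpha`.
#' Adjacency is re-checked at pop time, which makes the procedure independent
#' of the order in which series are listed.
#'
#' @inheritParams ctmi
#' @param ci_test optional perfect-information replacement for the statistical
#'   test, e.g. [dsep_oracle()]: a `function(p, q, R)` returning at least
#'   `p_value`, `value`, `gamma_bar`, `lambda_pq`, `lambda_qp`.
#' @return a `ctmi_skeleton` list: `graph` (skeleton [summary_graph]),
#'   `sepsets` (named list), `cache` (per-pair CTMI geometry, kept for the
#'   entropy-reduction rules), `stats` (tibble of executed tests), and
#'   `n_tests`.
#' @export
build_skeleton <- function(panel, space = search_space(),
                           cfg = estimator_config(), ci_test = NULL) {
  panel <- as_ts_panel(panel)
  space <- as_search_space(space); cfg <- as_estimator_config(cfg)
  if (is.null(ci_test)) panel <- prepare_panel(panel, seed = jitter_seed(cfg))
  nodes <- series_names(panel)
  if (length(nodes) < 2L) abort("need at least 2 series")
  g <- summary_graph(nodes, "skeleton", complete = TRUE)
  sepsets <- list()
  cache <- list() # per-pair geometry: p, q, gamma_bar, lambdas, value, sample
  pvals <- list()
  stats_rows <- list()
  n_tests <- 0L

  measure <- function(p, q, R) {
    key <- paste(sg_edge_key(p, q), paste(sort(R), collapse = ","), sep = "#")
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- tryCatch({
      if (!is.null(ci_test)) {
        o <- ci_test(p, q, R)
        list(value = o$value, p_value = o$p_value,
             gamma_bar = o$gamma_bar %||% 0L,
             lambda_pq = o$lambda_pq %||% 1L, lambda_qp = o$lambda_qp %||% 1L,
             sample = NULL)
      } else if (length(R) == 0L) {
        r <- ctmi(panel, min(p, q), max(p, q), space, cfg)
        list(value = r$value_raw, p_value = NA_real_,
             gamma_bar = r$gamma_bar, lambda_pq = r$lambda_bar_pq,
             lambda_qp = r$lambda_bar_qp, sample = r$sample,
             res = r,
             p = r$p, q = r$q)
      } else {
        base <- cache[[paste(sg_edge_key(p, q), "", sep = "#")]]
        base_res <- structure(list(
          p = base$p, q = base$q, gamma_bar = base$gamma_bar,
          lambda_bar_pq = base$lambda_pq, lambda_bar_qp = base$lambda_qp,
          value = max(base$value, 0), value_raw = base$value,
          grid = NULL, sample = base$sample), class = "ctmi_result")
        if (base_res$p != min(p, q)) base_res <- flip_ctmi(base_res)
        r <- conditional_ctmi(panel, min(p, q), max(p, q), sort(R),
                              base = base_res, space = space, cfg = cfg)
        list(value = r$value_raw, p_value = NA_real_,
             gamma_bar = base$gamma_bar, lambda_pq = base$lambda_pq,
             lambda_qp = base$lambda_qp, sample = r$sample,
             p = base$p, q = base$q)
      }
    }, error = function(e) {
      warn(sprintf("CTMI evaluation failed for (%s, %s | %s): %s", p, q,
                   paste(R, collapse = ","), conditionMessage(e)),
           class = "ctmi_test_failure")
      NULL
    })
    if (!is.null(out) && is.null(ci_test) && length(R) == 0L) {
      # canonical orientation for the geometry cache
      if (out$p != min(p, q)) {
        out$gamma_bar <- -out$gamma_bar
        lp <- out$lambda_pq; out$lambda_pq <- out$lambda_qp; out$lambda_qp <- lp
        out$p <- min(p, q); out$q <- max(p, q)
      }
    }
    if (!is.null(ci_test) && length(R) == 0L) {
      gb <- out$gamma_bar
      if (p != min(p, q)) gb <- -gb
      out$p <- min(p, q); out$q <- max(p, q); out$gamma_bar <- gb
    }
    cache[[key]] <<- out
    out
  }

  p_value_of <- function(p, q, R, ent) {
    key <- paste(sg_edge_key(p, q), paste(sort(R), collapse = ","), sep = "#")
    if (!is.null(pvals[[key]])) return(pvals[[key]])
    n_tests <<- n_tests + 1L
    pv <- if (!is.na(ent$p_value)) {
      ent$p_value
    } else if (length(R) == 0L) {
      ctmi_max_test(panel, ent$res, space, cfg,
                    seed = pair_seed(cfg$seed, p, q, R))$p_value
    } else {
      test_cfg <- cfg
      test_cfg$seed <- pair_seed(cfg$seed, p, q, R)
      js <- ent$sample
      local_permutation_test(js$x, js$y, joint_sample_z(js),
                             test_cfg)$p_value
    }
    pvals[[key]] <<- pv
    stats_rows[[length(stats_rows) + 1L]] <<- tibble::tibble(
      p = min(p, q), q = max(p, q),
      cond = paste(sort(R), collapse = ","),
      value = max(ent$value, 0), p_value = pv)
    pv
  }

  lag_admissible <- function(r, p, q) {
    ent_p <- measure(r, p, character(0))
    ent_q <- measure(r, q, character(0))
    g_rp <- if (is.null(ent_p)) 0L
            else if (ent_p$p == r) ent_p$gamma_bar else -ent_p$gamma_bar
    g_rq <- if (is.null(ent_q)) 0L
            else if (ent_q$p == r) ent_q$gamma_bar else -ent_q$gamma_bar
    g_rp >= 0L || g_rq >= 0L
  }

  n <- 0L
  repeat {
    degs <- vapply(nodes, function(v) length(sg_adjacent(g, v)), integer(1))
    if (!any(degs >= n + 1L)) break
    D <- list()
    for (q in nodes[degs >= n + 1L]) {
      for (p in sg_adjacent(g, q)) {
        pool <- setdiff(sg_adjacent(g, q), p)
        if (length(pool) < n) next
        subsets <- if (n == 0L) list(character(0))
                   else utils::combn(pool, n, simplify = FALSE)
        for (R in subsets) {
          if (n > 0L && !all(vapply(R, lag_admissible, logical(1), p, q))) {
            next
          }
          ent <- measure(p, q, R)
          if (is.null(ent)) next
          D[[length(D) + 1L]] <- list(q = q, p = p, R = R, y = ent$value)
        }
      }
    }
    if (length(D)) {
      ord <- order(vapply(D, `[[`, numeric(1), "y"))
      for (item in D[ord]) {
        p <- item$p; q <- item$q; R <- item$R
        if (!sg_has_edge(g, p, q)) next
        if (!all(R %in% sg_adjacent(g, q))) next
        ent <- measure(p, q, R)
        pv <- p_value_of(p, q, R, ent)
        if (pv > cfg$alpha) {
          g <- sg_remove_edge(g, p, q)
          sepsets[[sepset_key(p, q)]] <- sort(R)
        }
      }
    }
    n <- n + 1L
  }

  edge_cache <- cache[grepl("#$", names(cache))]
  names(edge_cache) <- sub("#$", "", names(edge_cache))
  structure(list(
    graph = g, sepsets = sepsets, cache = edge_cache,
    full_cache = cache, pvals = pvals,
    stats = dplyr::bind_rows(stats_rows), n_tests = n_tests,
    panel = panel, space = space, cfg = cfg, ci_test = ci_test
  ), class = "ctmi_skeleton")
}

#' PCTMI: summary causal graph discovery under causal sufficiency
#'
#' Learns a summary causal graph over the series of a panel: a
#' [build_skeleton()] pass with CTMI permutation tests, then orientation.
#' Lagged edges without possible spurious correlations are oriented along
#' their optimal lag before collider detection (empirically more reliable on
#' finite samples), then the classical propagation rules run to a fixed
#' point, and finally the entropy-reduction rules orient remaining edges from
#' the optimal lag or, at lag zero, the asymmetry of the optimal windows.
#' All lagged relations come out oriented; instantaneous ones may stay
#' undirected.
#'
#' @inheritParams build_skeleton
#' @param er_first apply the lag-orientation rule before collider detection.
#' @return a [summary_graph] in cpdag mode, with attributes `sepsets`,
#'   `stats` (per-edge geometry and p-values) and `n_tests`.
#' @examples
#' spec <- builtin_structures()$fork
#' g <- pctmi(generate_panel(spec, 100, seed = 1)$panel,
#'            ci_test = dsep_oracle(spec))
#' tidy(g)
#' @export
pctmi <- function(panel, space = search_space(), cfg = estimator_config(),
                  ci_test = NULL, er_first = TRUE) {
  sk <- build_skeleton(panel, space, cfg, ci_test)
  g <- sk$graph
  g$mode <- "cpdag"
  if (er_first) g <- apply_er_rules(g, sk$cache, lagged_only = TRUE)
  g <- apply_pc_rules(g, sk$sepsets, rule0 = TRUE)
  g <- apply_er_rules(g, sk$cache)
  attr(g, "sepsets") <- sk$sepsets
  attr(g, "stats") <- skeleton_edge_stats(sk, g)
  attr(g, "n_tests") <- sk$n_tests
  g
}

skeleton_edge_stats <- function(sk, g) {
  ed <- sg_pairs(g)
  rows <- purrr::pmap(ed, function(p, q) {
    if (!sg_has_edge(g, p, q)) return(NULL)
    ent <- sk$cache[[sg_edge_key(p, q)]]
    if (is.null(ent)) return(NULL)
    tibble::tibble(p = p, q = q, value = max(ent$value, 0),
                   gamma_bar = ent$gamma_bar, lambda_pq = ent$lambda_pq,
                   lambda_qp = ent$lambda_qp,
                   p_value = sk$pvals[[paste(sg_edge_key(p, q), "",
                                             sep = "#")]] %||% NA_real_)
  })
  dplyr::bind_rows(rows)
}

#' FCITMI: summary causal graph discovery with hidden common causes
#'
#' The latent-variable extension: after the same skeleton phase as [pctmi()],
#' unshielded colliders are detected, Possible-Dsep sets are formed, and
#' additional edges are removed by CTMI tests conditioned on subsets of those
#' sets (growing cardinality, ascending-value pop order, capped at
#' `pds_max`).  All endpoint marks are then reset to circles, colliders are
#' re-detected, the FCI arrowhead/tail rules (without the selection-bias
#' rules) run to a fixed point, and the latent entropy-reduction rules add
#' arrowheads along positive optimal lags or window asymmetries for pairs
#' without possible spurious correlations.
#'
#' @inheritParams pctmi
#' @param pds_max cap on the cardinality of Possible-Dsep conditioning
#'   subsets.
#' @return a [summary_graph] in pag mode (marks tail / arrow / circle), with
#'   the same attributes as [pctmi()].
#' @export
fcitmi <- function(panel, space = search_space(), cfg = estimator_config(),
                   ci_test = NULL, pds_max = 3L) {
  sk <- build_skeleton(panel, space, cfg, ci_test)
  g <- sk$graph
  g$mode <- "pag"
  nodes <- g$nodes
  # circles everywhere, then collider detection to shape Possible-Dsep sets
  for (i in seq_len(nrow(sg_pairs(g)))) {
    pr <- sg_pairs(g)
    p <- pr$p[i]; q <- pr$q[i]
    if (sg_has_edge(g, p, q)) g <- sg_add_edge(g, p, q, MARK_CIRCLE,
                                               MARK_CIRCLE)
  }
  sepsets <- sk$sepsets
  g <- fci_rule0(g, sepsets)

  # Possible-Dsep removals, reusing the skeleton's measure/p-value machinery
  cache <- sk$full_cache
  pvals <- sk$pvals
  cfg <- sk$cfg; space <- sk$space; panel <- sk$panel; ci_test <- sk$ci_test
  n_tests <- sk$n_tests

  measure_pd <- function(p, q, R) {
    key <- paste(sg_edge_key(p, q), paste(sort(R), collapse = ","), sep = "#")
    if (!is.null(cache[[key]])) return(cache[[key]])
    out <- tryCatch({
      if (!is.null(ci_test)) {
        o <- ci_test(p, q, R)
        list(value = o$value, p_value = o$p_value, sample = NULL)
      } else {
        base <- cache[[paste(sg_edge_key(p, q), "", sep = "#")]]
        base_res <- structure(list(
          p = base$p, q = base$q, gamma_bar = base$gamma_bar,
          lambda_bar_pq = base$lambda_pq, lambda_bar_qp = base$lambda_qp,
          value = max(base$value, 0), value_raw = base$value,
          grid = NULL, sample = base$sample), class = "ctmi_result")
        r <- conditional_ctmi(panel, base_res$p, base_res$q, sort(R),
                              base = base_res, space = space, cfg = cfg)
        list(value = r$value_raw, p_value = NA_real_, sample = r$sample)
      }
    }, error = function(e) {
      warn(conditionMessage(e), class = "ctmi_test_failure")
      NULL
    })
    cache[[key]] <<- out
    out
  }

  max_n <- min(pds_max, length(nodes) - 2L)
  for (n in seq_len(max(max_n, 0L))) {
    D <- list()
    pr <- sg_pairs(g)
    for (i in seq_len(nrow(pr))) {
      p <- pr$p[i]; q <- pr$q[i]
      if (!sg_has_edge(g, p, q)) next
      pool <- union(possible_dsep(g, p, q), possible_dsep(g, q, p))
      pool <- setdiff(pool, c(p, q))
      if (length(pool) < n) next
      for (R in utils::combn(pool, n, simplify = FALSE)) {
        ent <- measure_pd(p, q, R)
        if (is.null(ent)) next
        D[[length(D) + 1L]] <- list(p = p, q = q, R = R, y = ent$value)
      }
    }
    if (length(D) == 0L) next
    ord <- order(vapply(D, `[[`, numeric(1), "y"))
    for (item in D[ord]) {
      p <- item$p; q <- item$q; R <- item$R
      if (!sg_has_edge(g, p, q)) next
      key <- paste(sg_edge_key(p, q), paste(sort(R), collapse = ","),
                   sep = "#")
      if (!is.null(pvals[[key]])) next
      ent <- measure_pd(p, q, R)
      n_tests <- n_tests + 1L
      pv <- if (!is.na(ent$p_value)) ent$p_value else {
        test_cfg <- cfg
        test_cfg$seed <- pair_seed(cfg$seed, p, q, R)
        js <- ent$sample
        local_permutation_test(js$x, js$y, joint_sample_z(js),
                               test_cfg)$p_value
      }
      pvals[[key]] <- pv
      if (pv > cfg$alpha) {
        g <- sg_remove_edge(g, p, q)
        sepsets[[sepset_key(p, q)]] <- sort(R)
      }
    }
  }

  # reorient everything as o-o and run the full FCI rule set
  pr <- sg_pairs(g)
  for (i in seq_len(nrow(pr))) {
    if (sg_has_edge(g, pr$p[i], pr$q[i])) {
      g <- sg_add_edge(g, pr$p[i], pr$q[i], MARK_CIRCLE, MARK_CIRCLE)
    }
  }
  g$conflicted <- character(0)
  g <- fci_rule0(g, sepsets)
  g <- apply_fci_rules(g, sepsets)
  g <- apply_ler_rules(g, sk$cache)
  attr(g, "sepsets") <- sepsets
  attr(g, "stats") <- skeleton_edge_stats(sk, g)
  attr(g, "n_tests") <- n_tests
  g
}
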