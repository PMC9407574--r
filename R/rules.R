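# --- path predicates -------------------------------------------------------

#' Possible spurious correlation between two adjacent nodes
#'
#' True when some path between `p` and `q` other than the edge `p - q` itself
#' contains no collider, so that part of the observed association between the
#' two series could travel around the direct edge.  The entropy-reduction
#' orientation rules only fire on pairs without such paths.  A node is a
#' collider on a path only when both path edges carry determined arrowheads
#' into it; circle marks count as non-colliders, which makes the check
#' conservative.
#'
#' @param g a [summary_graph].
#' @param p,q adjacent node names.
#' @return logical flag.
#' @export
possible_spurious_correlation <- function(g, p, q) {
  ig <- sg_igraph(g)
  paths <- igraph::all_simple_paths(ig, from = p, to = q, mode = "all")
  for (path in paths) {
    nodes <- names(path)
    if (length(nodes) <= 2L) next # the direct edge
    interior <- seq(2L, length(nodes) - 1L)
    collider <- vapply(interior, function(i) {
      s <- nodes[i]
      sg_mark_at(g, nodes[i - 1L], s) == MARK_ARROW &&
        sg_mark_at(g, nodes[i + 1L], s) == MARK_ARROW
    }, logical(1))
    if (!any(collider)) return(TRUE)
  }
  FALSE
}

#' Possible-Dsep set of a pair
#'
#' Nodes `r` reachable from `p` along a path on which every consecutive triple
#' `<w, s, v>` either has `s` as a collider or has `w` and `v` adjacent.  Such
#' nodes can act as separators under latent confounding and are the candidate
#' conditioning pool of the second removal phase of [fcitmi()].
#'
#' @inheritParams possible_spurious_correlation
#' @return character vector of node names.
#' @export
possible_dsep <- function(g, p, q) {
  reached <- character(0)
  # states are (prev, cur) legs of a path from p
  seen <- character(0)
  queue <- purrr::map(sg_adjacent(g, p), function(m) c(p, m))
  while (length(queue)) {
    st <- queue[[1]]; queue <- queue[-1]
    key <- paste(st, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    w <- st[[1]]; s <- st[[2]]
    reached <- union(reached, s)
    for (v in sg_adjacent(g, s)) {
      if (v == w) next
      collider <- sg_mark_at(g, w, s) == MARK_ARROW &&
        sg_mark_at(g, v, s) == MARK_ARROW
      if (collider || sg_has_edge(g, w, v)) {
        queue <- c(queue, list(c(s, v)))
      }
    }
  }
  setdiff(reached, c(p, q))
}

sepset_key <- sg_edge_key

get_sepset <- function(sepsets, p, q) sepsets[[sepset_key(p, q)]]

in_sepset <- function(sepsets, p, q, r) {
  ss <- get_sepset(sepsets, p, q)
  !is.null(ss) && r %in% ss
}

unshielded_triples <- function(g) {
  out <- list()
  for (r in g$nodes) {
    adj <- sg_adjacent(g, r)
    if (length(adj) < 2L) next
    cmb <- utils::combn(adj, 2L)
    for (i in seq_len(ncol(cmb))) {
      p <- cmb[1, i]; q <- cmb[2, i]
      if (!sg_has_edge(g, p, q)) {
        out[[length(out) + 1L]] <- c(p, r, q)
      }
    }
  }
  out
}

# --- PC rules (CPDAG mode) -------------------------------------------------

#' Orientation rules of the summary-graph learners
#'
#' `apply_pc_rules()` runs the classical constraint-based orientation on a
#' skeleton: unshielded triples `p - r - q` whose middle node is outside the
#' recorded separating set become colliders `p -> r <- q` (rule 0, applied
#' once), then three propagation rules run to a fixed point: chain completion
#' `p -> r - q  =>  r -> q` when `r` separates the pair; orienting `p - q` as
#' `p -> q` when a directed path already leads from `p` to `q` (acyclicity);
#' and the double-collider rule `s -> r` when `p -> r <- q` and `p - s - q`.
#' Existing arrowheads are never removed; contradictory demands revert the
#' edge to undirected with a warning.
#'
#' `apply_er_rules()` orients remaining undirected edges from the CTMI
#' geometry cached at skeleton time: an edge whose endpoints have no
#' [possible_spurious_correlation()] is oriented along a positive optimal lag
#' (entropy-reduction rule 0) or, at lag zero, from the strictly smaller to
#' the strictly larger optimal window (rule 1).
#'
#' @param g a [summary_graph] in cpdag mode.
#' @param sepsets named list of separating sets as returned by
#'   [build_skeleton()].
#' @param rule0 also apply the collider rule (set `FALSE` when colliders were
#'   already oriented).
#' @return the oriented [summary_graph].
#' @export
apply_pc_rules <- function(g, sepsets, rule0 = TRUE) {
  if (rule0) {
    for (tr in unshielded_triples(g)) {
      if (!in_sepset(sepsets, tr[1], tr[3], tr[2])) {
        g <- cpdag_orient(g, tr[1], tr[2])
        g <- cpdag_orient(g, tr[3], tr[2])
      }
    }
  }
  repeat {
    before <- g$marks
    g <- pc_rule1(g, sepsets)
    g <- pc_rule2(g)
    g <- pc_rule3(g)
    if (identical(before, g$marks)) break
  }
  g
}

sg_is_directed <- function(g, p, q) {
  sg_mark_at(g, q, p) == MARK_TAIL && sg_mark_at(g, p, q) == MARK_ARROW
}

sg_is_undirected <- function(g, p, q) {
  sg_mark_at(g, q, p) == MARK_TAIL && sg_mark_at(g, p, q) == MARK_TAIL
}

pc_rule1 <- function(g, sepsets) {
  for (tr in unshielded_triples(g)) {
    for (ord in list(tr, rev(tr))) {
      p <- ord[1]; r <- ord[2]; q <- ord[3]
      if (sg_is_directed(g, p, r) && sg_is_undirected(g, r, q) &&
          in_sepset(sepsets, p, q, r)) {
        g <- cpdag_orient(g, r, q)
      }
    }
  }
  g
}

directed_subgraph <- function(g) {
  ed <- tidy(g)
  ed <- ed[ed$type == "directed", c("from", "to"), drop = FALSE]
  igraph::graph_from_data_frame(ed, directed = TRUE,
                                vertices = data.frame(name = g$nodes))
}

pc_rule2 <- function(g) {
  dg <- directed_subgraph(g)
  dist <- igraph::distances(dg, mode = "out")
  for (pr_i in seq_len(nrow(pr <- sg_pairs(g)))) {
    p <- pr$p[pr_i]; q <- pr$q[pr_i]
    if (!sg_has_edge(g, p, q) || !sg_is_undirected(g, p, q)) next
    if (is.finite(dist[p, q]) && dist[p, q] >= 1) {
      g <- cpdag_orient(g, p, q)
    } else if (is.finite(dist[q, p]) && dist[q, p] >= 1) {
      g <- cpdag_orient(g, q, p)
    }
  }
  g
}

pc_rule3 <- function(g) {
  for (r in g$nodes) {
    into_r <- g$nodes[vapply(g$nodes, function(v) {
      v != r && sg_has_edge(g, v, r) && sg_mark_at(g, v, r) == MARK_ARROW
    }, logical(1))]
    if (length(into_r) < 2L) next
    und_r <- g$nodes[vapply(g$nodes, function(s) {
      s != r && sg_has_edge(g, s, r) && sg_is_undirected(g, s, r)
    }, logical(1))]
    for (s in und_r) {
      pool <- setdiff(into_r, s)
      if (length(pool) < 2L) next
      cmb <- utils::combn(pool, 2L)
      for (i in seq_len(ncol(cmb))) {
        p <- cmb[1, i]; q <- cmb[2, i]
        if (sg_has_edge(g, p, q)) next # collider must be unshielded
        if (sg_has_edge(g, s, p) && sg_is_undirected(g, s, p) &&
            sg_has_edge(g, s, q) && sg_is_undirected(g, s, q)) {
          g <- cpdag_orient(g, s, r)
        }
      }
    }
  }
  g
}

# --- entropy-reduction rules -----------------------------------------------

cache_geometry <- function(cache, p, q) {
  ent <- cache[[sg_edge_key(p, q)]]
  if (is.null(ent)) return(NULL)
  if (ent$p == p) ent
  else list(p = p, q = q, gamma_bar = -ent$gamma_bar,
            lambda_pq = ent$lambda_qp, lambda_qp = ent$lambda_pq,
            value = ent$value)
}

#' @rdname apply_pc_rules
#' @param cache per-pair CTMI geometry from [build_skeleton()].
#' @param lagged_only restrict to edges with a nonzero optimal lag (the
#'   pre-collider pass).
#' @export
apply_er_rules <- function(g, cache, lagged_only = FALSE) {
  pr <- sg_pairs(g)
  for (i in seq_len(nrow(pr))) {
    p <- pr$p[i]; q <- pr$q[i]
    if (!sg_has_edge(g, p, q) || !sg_is_undirected(g, p, q)) next
    geo <- cache_geometry(cache, p, q)
    if (is.null(geo)) next
    if (lagged_only && geo$gamma_bar == 0L) next
    if (possible_spurious_correlation(g, p, q)) next
    if (geo$gamma_bar > 0L) {
      g <- cpdag_orient(g, p, q)
    } else if (geo$gamma_bar < 0L) {
      g <- cpdag_orient(g, q, p)
    } else if (geo$lambda_pq < geo$lambda_qp) {
      g <- cpdag_orient(g, p, q)
    } else if (geo$lambda_qp < geo$lambda_pq) {
      g <- cpdag_orient(g, q, p)
    }
  }
  g
}

# latent variant: only the arrowhead at the effect end is claimed
apply_ler_rules <- function(g, cache) {
  pr <- sg_pairs(g)
  for (i in seq_len(nrow(pr))) {
    p <- pr$p[i]; q <- pr$q[i]
    if (!sg_has_edge(g, p, q)) next
    if (sg_mark_at(g, p, q) != MARK_CIRCLE &&
        sg_mark_at(g, q, p) != MARK_CIRCLE) next
    geo <- cache_geometry(cache, p, q)
    if (is.null(geo)) next
    if (possible_spurious_correlation(g, p, q)) next
    if (geo$gamma_bar > 0L) {
      g <- pag_set_mark(g, p, q, MARK_ARROW)
    } else if (geo$gamma_bar < 0L) {
      g <- pag_set_mark(g, q, p, MARK_ARROW)
    } else if (geo$lambda_pq < geo$lambda_qp) {
      g <- pag_set_mark(g, p, q, MARK_ARROW)
    } else if (geo$lambda_qp < geo$lambda_pq) {
      g <- pag_set_mark(g, q, p, MARK_ARROW)
    }
  }
  g
}

# --- FCI rules (PAG mode) --------------------------------------------------

fci_rule0 <- function(g, sepsets) {
  for (tr in unshielded_triples(g)) {
    if (!in_sepset(sepsets, tr[1], tr[3], tr[2])) {
      g <- pag_set_mark(g, tr[1], tr[2], MARK_ARROW)
      g <- pag_set_mark(g, tr[3], tr[2], MARK_ARROW)
    }
  }
  g
}

#' FCI orientation rules for the latent-variable learner
#'
#' Applies, to a fixed point, the arrowhead/tail completion rules used by
#' [fcitmi()]: collider propagation on unshielded triples, the directed-triple
#' rule, the double-collider rule, the discriminating-path rule, and the three
#' tail rules based on uncovered potentially directed paths.  The
#' selection-bias rules are intentionally absent.  Collider detection itself
#' (`rule0 = TRUE`) can be included for standalone use.
#'
#' @param g a [summary_graph] in pag mode.
#' @param sepsets named list of separating sets.
#' @param rule0 also orient unshielded colliders first.
#' @return the oriented [summary_graph].
#' @export
apply_fci_rules <- function(g, sepsets, rule0 = FALSE) {
  if (rule0) g <- fci_rule0(g, sepsets)
  repeat {
    before <- g$marks
    g <- fci_rule1(g, sepsets)
    g <- fci_rule2(g)
    g <- fci_rule3(g)
    g <- fci_rule4(g, sepsets)
    g <- fci_rule8(g)
    g <- fci_rule9(g)
    g <- fci_rule10(g)
    if (identical(before, g$marks)) break
  }
  g
}

fci_rule1 <- function(g, sepsets) {
  for (tr in unshielded_triples(g)) {
    for (ord in list(tr, rev(tr))) {
      p <- ord[1]; r <- ord[2]; q <- ord[3]
      if (sg_mark_at(g, p, r) == MARK_ARROW &&
          sg_mark_at(g, q, r) == MARK_CIRCLE &&
          in_sepset(sepsets, p, q, r)) {
        g <- pag_set_mark(g, q, r, MARK_TAIL)
        g <- pag_set_mark(g, r, q, MARK_ARROW)
      }
    }
  }
  g
}

fci_rule2 <- function(g) {
  for (p in g$nodes) for (q in g$nodes) {
    if (p == q || !sg_has_edge(g, p, q)) next
    if (sg_mark_at(g, p, q) != MARK_CIRCLE) next
    for (r in setdiff(g$nodes, c(p, q))) {
      if (!sg_has_edge(g, p, r) || !sg_has_edge(g, r, q)) next
      chain1 <- sg_is_directed_pag(g, p, r) &&
        sg_mark_at(g, r, q) == MARK_ARROW
      chain2 <- sg_mark_at(g, p, r) == MARK_ARROW &&
        sg_is_directed_pag(g, r, q)
      if (chain1 || chain2) {
        g <- pag_set_mark(g, p, q, MARK_ARROW)
        break
      }
    }
  }
  g
}

sg_is_directed_pag <- function(g, p, q) {
  sg_mark_at(g, q, p) == MARK_TAIL && sg_mark_at(g, p, q) == MARK_ARROW
}

fci_rule3 <- function(g) {
  for (r in g$nodes) for (s in setdiff(g$nodes, r)) {
    if (!sg_has_edge(g, s, r) || sg_mark_at(g, s, r) != MARK_CIRCLE) next
    others <- setdiff(g$nodes, c(r, s))
    if (length(others) < 2L) next
    cmb <- utils::combn(others, 2L)
    for (i in seq_len(ncol(cmb))) {
      p <- cmb[1, i]; q <- cmb[2, i]
      if (sg_has_edge(g, p, q)) next
      ok <- sg_has_edge(g, p, r) && sg_has_edge(g, q, r) &&
        sg_mark_at(g, p, r) == MARK_ARROW &&
        sg_mark_at(g, q, r) == MARK_ARROW &&
        sg_has_edge(g, p, s) && sg_has_edge(g, q, s) &&
        sg_mark_at(g, p, s) == MARK_CIRCLE &&
        sg_mark_at(g, q, s) == MARK_CIRCLE
      if (ok) g <- pag_set_mark(g, s, r, MARK_ARROW)
    }
  }
  g
}

fci_rule4 <- function(g, sepsets) {
  for (r in g$nodes) for (q in setdiff(g$nodes, r)) {
    if (!sg_has_edge(g, r, q) || sg_mark_at(g, q, r) != MARK_CIRCLE) next
    found <- find_discriminating_path(g, r, q)
    if (is.null(found)) next
    if (in_sepset(sepsets, found$p, q, r)) {
      g <- pag_set_mark(g, q, r, MARK_TAIL)
      g <- pag_set_mark(g, r, q, MARK_ARROW)
    } else {
      s <- found$s
      g <- pag_set_mark(g, r, s, MARK_ARROW)
      g <- pag_set_mark(g, s, r, MARK_ARROW)
      g <- pag_set_mark(g, q, r, MARK_ARROW)
      g <- pag_set_mark(g, r, q, MARK_ARROW)
    }
  }
  g
}

# search for a discriminating path <p, ..., s, r, q> for the edge r *-o q:
# interior vertices are colliders and parents of q; p is not adjacent to q
find_discriminating_path <- function(g, r, q) {
  grow <- function(head, path) {
    # head is a collider-parent chain end; look for predecessors u *-> head
    for (u in setdiff(g$nodes, c(path, q))) {
      if (!sg_has_edge(g, u, head)) next
      if (sg_mark_at(g, u, head) != MARK_ARROW) next
      if (!sg_has_edge(g, u, q)) {
        if (length(path) >= 2L) {
          return(list(p = u, s = path[[1]], path = c(u, path, q)))
        }
        next
      }
      # u stays interior: must be a collider on the path and a parent of q
      if (sg_mark_at(g, head, u) == MARK_ARROW && sg_is_directed_pag(g, u, q)) {
        found <- grow(u, c(u, path))
        if (!is.null(found)) return(found)
      }
    }
    NULL
  }
  grow(r, r)
}

fci_rule8 <- function(g) {
  for (p in g$nodes) for (q in setdiff(g$nodes, p)) {
    if (!sg_has_edge(g, p, q)) next
    if (!(sg_mark_at(g, q, p) == MARK_CIRCLE &&
          sg_mark_at(g, p, q) == MARK_ARROW)) next # p o-> q
    for (r in setdiff(g$nodes, c(p, q))) {
      if (!sg_has_edge(g, p, r) || !sg_has_edge(g, r, q)) next
      first <- sg_is_directed_pag(g, p, r) ||
        (sg_mark_at(g, r, p) == MARK_TAIL &&
           sg_mark_at(g, p, r) == MARK_CIRCLE) # p -o r
      if (first && sg_is_directed_pag(g, r, q)) {
        g <- pag_set_mark(g, q, p, MARK_TAIL)
        break
      }
    }
  }
  g
}

# potentially directed step u *-* v: no arrowhead at u, no tail at v
pd_step <- function(g, u, v) {
  sg_has_edge(g, u, v) &&
    sg_mark_at(g, v, u) != MARK_ARROW && sg_mark_at(g, u, v) != MARK_TAIL
}

# uncovered potentially directed paths from `from` to `to`, avoiding the
# direct edge; returns the list of paths (vectors of node names)
upd_paths <- function(g, from, to) {
  out <- list()
  dfs <- function(path) {
    cur <- path[[length(path)]]
    for (v in g$nodes) {
      if (v %in% path) next
      if (length(path) == 1L && v == to) next # skip the direct edge
      if (!pd_step(g, cur, v)) next
      if (length(path) >= 2L &&
          sg_has_edge(g, path[[length(path) - 1L]], v)) next # covered triple
      new_path <- c(path, v)
      if (v == to) out[[length(out) + 1L]] <<- new_path
      else dfs(new_path)
    }
  }
  dfs(from)
  out
}

fci_rule9 <- function(g) {
  for (p in g$nodes) for (q in setdiff(g$nodes, p)) {
    if (!sg_has_edge(g, p, q)) next
    if (!(sg_mark_at(g, q, p) == MARK_CIRCLE &&
          sg_mark_at(g, p, q) == MARK_ARROW)) next
    paths <- upd_paths(g, p, q)
    hit <- purrr::detect(paths, function(path) {
      length(path) >= 3L && !sg_has_edge(g, path[[2L]], q)
    })
    if (!is.null(hit)) g <- pag_set_mark(g, q, p, MARK_TAIL)
  }
  g
}

fci_rule10 <- function(g) {
  for (p in g$nodes) for (q in setdiff(g$nodes, p)) {
    if (!sg_has_edge(g, p, q)) next
    if (!(sg_mark_at(g, q, p) == MARK_CIRCLE &&
          sg_mark_at(g, p, q) == MARK_ARROW)) next
    into_q <- g$nodes[vapply(g$nodes, function(v) {
      v != q && v != p && sg_has_edge(g, v, q) && sg_is_directed_pag(g, v, q)
    }, logical(1))]
    if (length(into_q) < 2L) next
    done <- FALSE
    cmb <- utils::combn(into_q, 2L)
    for (i in seq_len(ncol(cmb))) {
      r <- cmb[1, i]; s <- cmb[2, i]
      u1 <- c(upd_paths(g, p, r), if (pd_step(g, p, r)) list(c(p, r)))
      u2 <- c(upd_paths(g, p, s), if (pd_step(g, p, s)) list(c(p, s)))
      for (a in u1) for (b in u2) {
        mu <- a[[2L]]; om <- b[[2L]]
        if (mu != om && !sg_has_edge(g, mu, om)) {
          g <- pag_set_mark(g, q, p, MARK_TAIL)
          done <- TRUE
          break
        }
      }
      if (done) break
    }
  }
  g
}
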