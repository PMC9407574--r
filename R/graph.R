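# endpoint mark codes
MARK_NONE <- 0L
MARK_TAIL <- 1L
MARK_ARROW <- 2L
MARK_CIRCLE <- 3L

mark_chr <- c(`0` = "none", `1` = "tail", `2` = "arrow", `3` = "circle")

#' Summary causal graphs
#'
#' Nodes are whole time series; an edge means that some lagged instance of one
#' series causes the other.  Each edge endpoint carries a mark: a tail, an
#' arrowhead, or (in partial ancestral graphs) a circle for an undetermined
#' mark.  A directed edge is tail-to-arrow; arrowheads at both ends denote a
#' hidden common cause.  Every node implicitly carries a lag-1 self-loop
#' (first-order self-causation); self-loops are never tested or scored.
#'
#' @param nodes character vector of series names.
#' @param mode `"skeleton"`, `"cpdag"` or `"pag"`.
#' @param complete start from the complete graph (`TRUE`, the skeleton
#'   learner's starting point) or the empty graph.
#' @return a `summary_graph`.
#' @examples
#' g <- summary_graph(c("a", "b", "c"), complete = TRUE)
#' tidy(g)
#' @export
summary_graph <- function(nodes, mode = c("skeleton", "cpdag", "pag"),
                          complete = FALSE) {
  mode <- match.arg(mode)
  d <- length(nodes)
  fill <- if (!complete) MARK_NONE else if (mode == "pag") MARK_CIRCLE
          else MARK_TAIL
  marks <- matrix(fill, d, d, dimnames = list(nodes, nodes))
  diag(marks) <- MARK_NONE
  structure(list(
    nodes = nodes,
    marks = marks,
    mode = mode,
    self_loops = stats::setNames(rep(TRUE, d), nodes),
    conflicted = character(0)
  ), class = "summary_graph")
}

#' @rdname summary_graph
#' @param x,g a `summary_graph`.
#' @export
is_summary_graph <- function(x) inherits(x, "summary_graph")

#' @rdname summary_graph
#' @param p,q node names.
#' @export
sg_has_edge <- function(g, p, q) g$marks[p, q] != MARK_NONE

#' @rdname summary_graph
#' @export
sg_adjacent <- function(g, p) {
  g$nodes[g$marks[p, g$nodes] != MARK_NONE]
}

sg_edge_key <- function(p, q) paste(sort(c(p, q)), collapse = "\r")

sg_add_edge <- function(g, p, q,
                        mark_p = default_mark(g), mark_q = default_mark(g)) {
  g$marks[q, p] <- mark_p # mark at p on edge p-q
  g$marks[p, q] <- mark_q
  g
}

sg_remove_edge <- function(g, p, q) {
  g$marks[p, q] <- MARK_NONE
  g$marks[q, p] <- MARK_NONE
  g
}

default_mark <- function(g) if (g$mode == "pag") MARK_CIRCLE else MARK_TAIL

# mark at the `at` end of the edge between `at` and `other`
sg_mark_at <- function(g, other, at) g$marks[other, at]

#' @rdname summary_graph
#' @export
sg_edge_count <- function(g) sum(g$marks != MARK_NONE) / 2

# Orient p -> q in a CPDAG-mode graph.  An existing arrowhead is never
# removed or reversed: a demand contradicting one is ignored (logged once per
# edge), so earlier rules take precedence over later ones.
cpdag_orient <- function(g, p, q) {
  if (!sg_has_edge(g, p, q)) return(g)
  at_p <- sg_mark_at(g, q, p); at_q <- sg_mark_at(g, p, q)
  if (at_p == MARK_ARROW) { # already oriented q -> p: conflicting demand
    key <- sg_edge_key(p, q)
    if (!key %in% g$conflicted) {
      g$conflicted <- c(g$conflicted, key)
      warn(sprintf(
        "conflicting orientation demand %s -> %s ignored (edge is %s -> %s)",
        p, q, q, p), class = "ctmi_orientation_conflict")
    }
    return(g)
  }
  if (at_q == MARK_ARROW) return(g) # already as demanded
  sg_add_edge(g, p, q, MARK_TAIL, MARK_ARROW)
}

# Set the mark at the q end of edge p-q in a PAG-mode graph.  Determined
# marks (tail or arrow) are never rewritten; contradicting demands are
# ignored and logged once per edge.
pag_set_mark <- function(g, p, q, mark) {
  if (!sg_has_edge(g, p, q)) return(g)
  cur <- sg_mark_at(g, p, q)
  if (cur == mark) return(g)
  if (cur != MARK_CIRCLE) {
    key <- sg_edge_key(p, q)
    if (!key %in% g$conflicted) {
      g$conflicted <- c(g$conflicted, key)
      warn(sprintf("conflicting mark demand at %s on %s *-* %s ignored",
                   q, p, q), class = "ctmi_orientation_conflict")
    }
    return(g)
  }
  g$marks[p, q] <- mark
  g
}

sg_pairs <- function(g) {
  if (length(g$nodes) < 2L) {
    return(tibble::tibble(p = character(0), q = character(0)))
  }
  cmb <- utils::combn(g$nodes, 2L)
  tibble::tibble(p = cmb[1, ], q = cmb[2, ])
}

edge_type <- function(m1, m2) {
  dplyr::case_when(
    m1 == MARK_TAIL & m2 == MARK_ARROW ~ "directed",
    m1 == MARK_ARROW & m2 == MARK_TAIL ~ "directed",
    m1 == MARK_ARROW & m2 == MARK_ARROW ~ "bidirected",
    m1 == MARK_TAIL & m2 == MARK_TAIL ~ "undirected",
    m1 == MARK_CIRCLE & m2 == MARK_CIRCLE ~ "undetermined",
    TRUE ~ "partial"
  )
}

#' Tidy an inferred summary graph into an edge table
#'
#' @param x a [summary_graph].
#' @param ... unused.
#' @return a tibble with one row per edge: `from`, `to`, endpoint marks and an
#'   edge `type` (`directed` rows are normalized so `from` is the cause).
#' @export
tidy.summary_graph <- function(x, ...) {
  pr <- sg_pairs(x)
  out <- purrr::pmap_dfr(pr, function(p, q) {
    m_p <- sg_mark_at(x, q, p); m_q <- sg_mark_at(x, p, q)
    if (m_q == MARK_NONE) return(NULL)
    if (m_p == MARK_ARROW && m_q != MARK_ARROW) { # normalize direction
      tmp <- p; p <- q; q <- tmp
      tmp <- m_p; m_p <- m_q; m_q <- tmp
    }
    tibble::tibble(from = p, to = q,
                   mark_from = unname(mark_chr[as.character(m_p)]),
                   mark_to = unname(mark_chr[as.character(m_q)]),
                   type = edge_type(m_p, m_q))
  })
  if (nrow(out) == 0L) {
    out <- tibble::tibble(from = character(0), to = character(0),
                          mark_from = character(0), mark_to = character(0),
                          type = character(0))
  }
  out
}

#' @rdname tidy.summary_graph
#' @export
glance.summary_graph <- function(x, ...) {
  ed <- tidy(x)
  tibble::tibble(
    nodes = length(x$nodes),
    edges = nrow(ed),
    directed = sum(ed$type == "directed"),
    bidirected = sum(ed$type == "bidirected"),
    unoriented = sum(!ed$type %in% c("directed", "bidirected")),
    mode = x$mode
  )
}

#' @export
print.summary_graph <- function(x, ...) {
  cat(sprintf("Summary causal graph (%s): %d nodes, %d edges\n",
              x$mode, length(x$nodes), sg_edge_count(x)))
  ed <- tidy(x)
  if (nrow(ed)) {
    glyph <- function(m1, m2) {
      left <- c(tail = "-", arrow = "<", circle = "o")[m1]
      right <- c(tail = "-", arrow = ">", circle = "o")[m2]
      paste0(left, "-", right)
    }
    for (i in seq_len(nrow(ed))) {
      cat(" ", ed$from[i], glyph(ed$mark_from[i], ed$mark_to[i]), ed$to[i],
          "\n")
    }
  }
  invisible(x)
}

#' Plot a summary graph
#'
#' Nodes on a circle, edges drawn with their endpoint marks (arrowheads for
#' arrows, open circles for undetermined marks).
#'
#' @param object a [summary_graph].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.summary_graph <- function(object, ...) {
  d <- length(object$nodes)
  ang <- seq(0, 2 * pi, length.out = d + 1L)[seq_len(d)]
  layout <- tibble::tibble(node = object$nodes, x = cos(ang), y = sin(ang))
  ed <- tidy(object)
  p <- ggplot2::ggplot(layout, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(ed)) {
    seg <- ed |>
      dplyr::left_join(layout, by = c(from = "node")) |>
      dplyr::rename(x0 = "x", y0 = "y") |>
      dplyr::left_join(layout, by = c(to = "node")) |>
      dplyr::mutate(
        # shrink segments so marks sit outside the node labels
        xa = .data$x0 + 0.12 * (.data$x - .data$x0),
        ya = .data$y0 + 0.12 * (.data$y - .data$y0),
        xb = .data$x + 0.12 * (.data$x0 - .data$x),
        yb = .data$y + 0.12 * (.data$y0 - .data$y)
      )
    p <- p + ggplot2::geom_segment(
      data = dplyr::filter(seg, .data$mark_to == "arrow"),
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      linewidth = 0.5) +
      ggplot2::geom_segment(
        data = dplyr::filter(seg, .data$mark_to != "arrow"),
        ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                     yend = .data$yb),
        linewidth = 0.5)
    circ <- dplyr::bind_rows(
      dplyr::filter(seg, .data$mark_from == "circle") |>
        dplyr::transmute(x = .data$xa, y = .data$ya),
      dplyr::filter(seg, .data$mark_to == "circle") |>
        dplyr::transmute(x = .data$xb, y = .data$yb))
    if (nrow(circ)) {
      p <- p + ggplot2::geom_point(data = circ, shape = 21, size = 2,
                                   fill = "white")
    }
  }
  p +
    ggplot2::geom_label(ggplot2::aes(label = .data$node)) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}

#' Write and read summary graphs
#'
#' `write_summary_graph()` writes a tab-separated edge list
#' (`source  target  mark_source  mark_target`) and, when `json` is given, a
#' JSON dump carrying nodes, mode, edges and any attached per-edge statistics.
#' `read_summary_graph()` reads either format back.
#'
#' @param g a [summary_graph].
#' @param path output TSV path.
#' @param json optional JSON path.
#' @return `g`, invisibly; `read_summary_graph()` returns a [summary_graph].
#' @export
write_summary_graph <- function(g, path, json = NULL) {
  ed <- tidy(g)
  readr::write_tsv(
    dplyr::transmute(ed, source = .data$from, target = .data$to,
                     mark_source = .data$mark_from,
                     mark_target = .data$mark_to),
    path)
  if (!is.null(json)) {
    payload <- list(nodes = g$nodes, mode = g$mode, edges = ed,
                    self_loops = as.list(g$self_loops))
    if (!is.null(attr(g, "stats"))) payload$stats <- attr(g, "stats")
    if (!is.null(attr(g, "sepsets"))) {
      payload$sepsets <- purrr::imap(attr(g, "sepsets"), function(v, k) {
        list(pair = strsplit(k, "\r", fixed = TRUE)[[1]], sepset = v)
      })
    }
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(g)
}

#' @rdname write_summary_graph
#' @param nodes node set for the TSV reader (edge lists do not mention
#'   isolated nodes); ignored for JSON input.
#' @param mode graph mode for the TSV reader.
#' @export
read_summary_graph <- function(path, nodes = NULL, mode = "cpdag") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    g <- summary_graph(payload$nodes, mode = payload$mode)
    ed <- payload$edges
  } else {
    ed <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    ed <- dplyr::rename(ed, from = "source", to = "target",
                        mark_from = "mark_source", mark_to = "mark_target")
    g <- summary_graph(nodes %||% sort(unique(c(ed$from, ed$to))), mode = mode)
  }
  code <- stats::setNames(as.integer(names(mark_chr)), mark_chr)
  if (!is.null(ed) && length(ed) && nrow(ed)) {
    for (i in seq_len(nrow(ed))) {
      g <- sg_add_edge(g, ed$from[i], ed$to[i],
                       code[[ed$mark_from[i]]], code[[ed$mark_to[i]]])
    }
  }
  g
}

# igraph view of the adjacencies (marks ignored), used for path searches
sg_igraph <- function(g) {
  ed <- tidy(g)
  igraph::graph_from_data_frame(
    ed[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = g$nodes))
}
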