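# small helpers to build graphs mark by mark
TAIL <- ctmi:::MARK_TAIL; ARROW <- ctmi:::MARK_ARROW; CIRC <- ctmi:::MARK_CIRCLE
edge <- function(g, p, q, mp = TAIL, mq = TAIL) ctmi:::sg_add_edge(g, p, q, mp, mq)

test_that("possible spurious correlation follows the collider-free-path rule", {
  g <- summary_graph(c("p", "q", "r"))
  g <- edge(g, "p", "q"); g <- edge(g, "p", "r"); g <- edge(g, "r", "q")
  expect_true(possible_spurious_correlation(g, "p", "q"))

  g2 <- summary_graph(c("p", "q", "r"))
  g2 <- edge(g2, "p", "q")
  g2 <- edge(g2, "p", "r", TAIL, ARROW) # p -> r
  g2 <- edge(g2, "q", "r", TAIL, ARROW) # q -> r: collider on the only path
  expect_false(possible_spurious_correlation(g2, "p", "q"))

  g3 <- summary_graph(c("p", "q", "r"))
  g3 <- edge(g3, "p", "q")
  expect_false(possible_spurious_correlation(g3, "p", "q"))
})

test_that("PC rule 0 orients unshielded colliders from sepsets", {
  g <- summary_graph(c("p", "r", "q"))
  g <- edge(g, "p", "r"); g <- edge(g, "q", "r")
  out <- apply_pc_rules(g, sepsets = list()) # r not in (empty) sepset
  expect_true(ctmi:::sg_is_directed(out, "p", "r"))
  expect_true(ctmi:::sg_is_directed(out, "q", "r"))

  ss <- list(); ss[[ctmi:::sepset_key("p", "q")]] <- "r"
  out2 <- apply_pc_rules(g, ss) # r separates: no collider, nothing fires
  expect_true(ctmi:::sg_is_undirected(out2, "p", "r"))
})

test_that("PC rules 1-3 propagate orientations", {
  # rule 1: p -> r - q with r in sepset(p, q) => r -> q
  g <- summary_graph(c("p", "r", "q"))
  g <- edge(g, "p", "r", TAIL, ARROW); g <- edge(g, "r", "q")
  ss <- list(); ss[[ctmi:::sepset_key("p", "q")]] <- "r"
  out <- apply_pc_rules(g, ss, rule0 = FALSE)
  expect_true(ctmi:::sg_is_directed(out, "r", "q"))

  # rule 2: directed path p -> r -> q plus edge p - q => p -> q
  g <- summary_graph(c("p", "r", "q"))
  g <- edge(g, "p", "r", TAIL, ARROW); g <- edge(g, "r", "q", TAIL, ARROW)
  g <- edge(g, "p", "q")
  out <- apply_pc_rules(g, list(), rule0 = FALSE)
  expect_true(ctmi:::sg_is_directed(out, "p", "q"))

  # rule 3: p -> r <- q, p - s - q unshielded, s - r => s -> r
  g <- summary_graph(c("p", "q", "r", "s"))
  g <- edge(g, "p", "r", TAIL, ARROW); g <- edge(g, "q", "r", TAIL, ARROW)
  g <- edge(g, "p", "s"); g <- edge(g, "q", "s"); g <- edge(g, "s", "r")
  out <- apply_pc_rules(g, list(), rule0 = FALSE)
  expect_true(ctmi:::sg_is_directed(out, "s", "r"))
})

test_that("ER rules orient by lag sign and window asymmetry", {
  cache <- list()
  cache[[ctmi:::sg_edge_key("p", "q")]] <-
    list(p = "p", q = "q", gamma_bar = 2L, lambda_pq = 1L, lambda_qp = 1L,
         value = 1)
  g <- summary_graph(c("p", "q"))
  g <- edge(g, "p", "q")
  out <- apply_er_rules(g, cache)
  expect_true(ctmi:::sg_is_directed(out, "p", "q"))

  cache[[ctmi:::sg_edge_key("p", "q")]]$gamma_bar <- 0L
  cache[[ctmi:::sg_edge_key("p", "q")]]$lambda_qp <- 2L
  out <- apply_er_rules(g, cache) # lag 0, smaller window on the cause side
  expect_true(ctmi:::sg_is_directed(out, "p", "q"))

  cache[[ctmi:::sg_edge_key("p", "q")]]$lambda_qp <- 1L
  out <- apply_er_rules(g, cache) # full tie: neither rule fires
  expect_true(ctmi:::sg_is_undirected(out, "p", "q"))

  # blocked by a possible spurious correlation
  cache[[ctmi:::sg_edge_key("p", "q")]]$gamma_bar <- 2L
  g3 <- summary_graph(c("p", "q", "r"))
  g3 <- edge(g3, "p", "q"); g3 <- edge(g3, "p", "r"); g3 <- edge(g3, "r", "q")
  out <- apply_er_rules(g3, cache)
  expect_true(ctmi:::sg_is_undirected(out, "p", "q"))
})

test_that("possible-Dsep collects collider and triangle paths", {
  g <- summary_graph(c("p", "s", "r", "q"), mode = "pag")
  g <- edge(g, "p", "s", CIRC, ARROW) # p *-> s
  g <- edge(g, "r", "s", CIRC, ARROW) # r *-> s: collider at s
  expect_true("r" %in% possible_dsep(g, "p", "q"))

  g2 <- summary_graph(c("p", "s", "r", "q"), mode = "pag")
  g2 <- edge(g2, "p", "s", CIRC, CIRC); g2 <- edge(g2, "s", "r", CIRC, CIRC)
  g2 <- edge(g2, "p", "r", CIRC, CIRC) # triangle: w, v adjacent
  expect_true("r" %in% possible_dsep(g2, "p", "q"))

  g3 <- summary_graph(c("p", "r", "q"), mode = "pag")
  g3 <- edge(g3, "p", "q", CIRC, CIRC)
  expect_false("r" %in% possible_dsep(g3, "p", "q"))
})

test_that("FCI rules 1-3 orient the documented patterns", {
  ss <- list(); ss[[ctmi:::sepset_key("p", "q")]] <- "r"
  g <- summary_graph(c("p", "r", "q"), mode = "pag")
  g <- edge(g, "p", "r", CIRC, ARROW) # p *-> r
  g <- edge(g, "r", "q", CIRC, CIRC)  # r o-o q
  out <- apply_fci_rules(g, ss)
  expect_equal(ctmi:::sg_mark_at(out, "q", "r"), TAIL)
  expect_equal(ctmi:::sg_mark_at(out, "r", "q"), ARROW)

  # rule 2: p -> r *-> q with p *-o q
  g <- summary_graph(c("p", "r", "q"), mode = "pag")
  g <- edge(g, "p", "r", TAIL, ARROW)
  g <- edge(g, "r", "q", CIRC, ARROW)
  g <- edge(g, "p", "q", CIRC, CIRC)
  out <- apply_fci_rules(g, list())
  expect_equal(ctmi:::sg_mark_at(out, "p", "q"), ARROW)

  # rule 3: p *-> r <-* q, p *-o s o-* q, s *-o r
  g <- summary_graph(c("p", "q", "r", "s"), mode = "pag")
  g <- edge(g, "p", "r", CIRC, ARROW); g <- edge(g, "q", "r", CIRC, ARROW)
  g <- edge(g, "p", "s", CIRC, CIRC); g <- edge(g, "q", "s", CIRC, CIRC)
  g <- edge(g, "s", "r", CIRC, CIRC)
  out <- apply_fci_rules(g, list())
  expect_equal(ctmi:::sg_mark_at(out, "s", "r"), ARROW)
})

test_that("rule application terminates and leaves valid cpdag marks", {
  withr::with_seed(40, {
    for (case in 1:10) {
      d <- sample(3:6, 1)
      nodes <- paste0("n", seq_len(d))
      g <- summary_graph(nodes, complete = FALSE)
      for (i in seq_len(d - 1)) for (j in seq((i + 1), d)) {
        if (runif(1) < 0.5) g <- edge(g, nodes[i], nodes[j])
      }
      ss <- list()
      out <- suppressWarnings(apply_pc_rules(g, ss))
      expect_true(all(out$marks %in% c(0L, TAIL, ARROW)))
      # no bidirected edges in cpdag mode
      for (i in seq_len(d - 1)) for (j in seq((i + 1), d)) {
        m1 <- ctmi:::sg_mark_at(out, nodes[j], nodes[i])
        m2 <- ctmi:::sg_mark_at(out, nodes[i], nodes[j])
        expect_false(m1 == ARROW && m2 == ARROW)
      }
    }
  })
})
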