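oracle_panel <- function(spec, seed = 1) {
  generate_panel(spec, n_time = 60, seed = seed)$panel
}

test_that("skeleton with a perfect oracle matches the true skeleton", {
  spec <- builtin_structures()$fork
  sk <- build_skeleton(oracle_panel(spec), ci_test = dsep_oracle(spec))
  ed <- tidy(sk$graph)
  expect_setequal(paste(ed$from, ed$to), c("X1 X2", "X1 X3"))
  expect_equal(sk$sepsets[[ctmi:::sepset_key("X2", "X3")]], "X1")
})

test_that("mutually independent series give an empty skeleton", {
  spec <- structure_spec(c("A", "B", "C"),
                         tibble::tibble(from = character(0),
                                        to = character(0)))
  sk <- build_skeleton(oracle_panel(spec), ci_test = dsep_oracle(spec))
  expect_equal(sg_edge_count(sk$graph), 0)
})

test_that("skeleton is invariant to the order series are listed", {
  spec <- builtin_structures()$fork
  pan <- oracle_panel(spec)
  oracle <- dsep_oracle(spec)
  canon <- function(g) {
    ed <- tidy(g)
    sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))
  }
  ref <- NULL
  for (ord in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1))) {
    sk <- build_skeleton(pan[, ord], ci_test = oracle)
    ed <- canon(sk$graph)
    if (is.null(ref)) ref <- ed else expect_identical(ed, ref)
  }
})

test_that("pctmi with a perfect oracle recovers the exact graphs", {
  st <- builtin_structures()
  for (nm in c("fork", "v_structure", "diamond")) {
    spec <- st[[nm]]
    g <- pctmi(oracle_panel(spec), ci_test = dsep_oracle(spec))
    truth <- generate_panel(spec, 60, seed = 1)$truth
    expect_equal(f1_directed(g, truth), 1)
    expect_identical(dplyr::arrange(tidy(g), from, to),
                     dplyr::arrange(tidy(truth), from, to))
  }
})

test_that("test count stays below the worst-case bound", {
  for (nm in c("fork", "v_structure", "diamond")) {
    spec <- builtin_structures()[[nm]]
    g <- pctmi(oracle_panel(spec), ci_test = dsep_oracle(spec))
    d <- length(spec$nodes)
    deg <- max(table(c(spec$edges$from, spec$edges$to)))
    bound <- d^2 * (d - 1)^(max(deg - 1, 0)) * factorial(max(deg - 1, 0))
    expect_lte(attr(g, "n_tests"), bound)
  }
})

test_that("pctmi orients a single lagged pair from the optimal lag", {
  pan <- lagged_pair_panel(800, lag = 1, coef = 1, seed = 3)
  g <- pctmi(pan, search_space(2), estimator_config(k = 10, B = 50, seed = 3))
  ed <- tidy(g)
  expect_equal(nrow(ed), 1)
  expect_identical(ed$from, "P")
  expect_identical(ed$to, "Q")
  expect_identical(ed$type, "directed")
})

test_that("fcitmi flags a hidden common cause with double arrowheads", {
  # observed roots C and D make both ends of the confounded pair colliders
  spec <- structure_spec(
    c("A", "B", "C", "D", "H"),
    tibble::tibble(from = c("C", "H", "H", "D"),
                   to = c("A", "A", "B", "B")),
    hidden = "H")
  obs_panel <- generate_panel(spec, 60, seed = 2)$panel
  g <- fcitmi(obs_panel, ci_test = dsep_oracle(spec))
  expect_equal(ctmi:::sg_mark_at(g, "A", "B"), ctmi:::MARK_ARROW)
  expect_equal(ctmi:::sg_mark_at(g, "B", "A"), ctmi:::MARK_ARROW)
  expect_true(all(g$marks %in% c(0L, ctmi:::MARK_TAIL, ctmi:::MARK_ARROW,
                                 ctmi:::MARK_CIRCLE)))
})

test_that("fcitmi matches the pctmi skeleton under causal sufficiency", {
  spec <- builtin_structures()$fork
  pan <- oracle_panel(spec)
  oracle <- dsep_oracle(spec)
  gp <- pctmi(pan, ci_test = oracle)
  gf <- fcitmi(pan, ci_test = oracle)
  adj <- function(g) dplyr::arrange(tidy(g)[, c("from", "to")], from, to)
  expect_identical(adj(gf), adj(gp))
})

test_that("latent entropy-reduction rule orients a lagged pair", {
  spec <- structure_spec(c("P", "Q"), tibble::tibble(from = "P", to = "Q"))
  pan <- oracle_panel(spec)
  g <- fcitmi(pan, ci_test = dsep_oracle(spec))
  expect_equal(ctmi:::sg_mark_at(g, "P", "Q"), ctmi:::MARK_ARROW)
})

test_that("skeleton never adds edges and caches every surviving edge", {
  spec <- builtin_structures()$diamond
  sk <- build_skeleton(oracle_panel(spec), ci_test = dsep_oracle(spec))
  ed <- tidy(sk$graph)
  expect_lte(nrow(ed), choose(4, 2))
  for (i in seq_len(nrow(ed))) {
    expect_false(is.null(sk$cache[[ctmi:::sg_edge_key(ed$from[i],
                                                      ed$to[i])]]))
  }
})
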