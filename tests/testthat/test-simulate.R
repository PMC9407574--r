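test_that("generator starts at zero and is reproducible under a seed", {
  spec <- builtin_structures()$fork
  a <- generate_panel(spec, 100, seed = 5)
  b <- generate_panel(spec, 100, seed = 5)
  expect_identical(a$panel, b$panel)
  expect_false(identical(a$panel, generate_panel(spec, 100, seed = 6)$panel))
  raw <- ctmi:::simulate_structural(spec, 50)
  expect_true(all(raw[1, ] == 0))
})

test_that("coefficients and innovations follow the stated law", {
  spec <- builtin_structures()$diamond
  withr::with_seed(10, {
    draws <- replicate(2000, sample(c(-1, 1), 1) *
                         runif(1, spec$coef_low, spec$coef_high))
  })
  expect_true(all(abs(draws) >= 0.1 & abs(draws) <= 1))
  withr::with_seed(2, {
    innov <- 0.1 * rnorm(1e5, 0, sqrt(15))
  })
  expect_equal(var(innov), 0.15, tolerance = 0.05 * 0.15)
})

test_that("builtin structures have the documented shapes", {
  st <- builtin_structures()
  expect_equal(nrow(st$fork$edges), 2)
  expect_equal(nrow(st$diamond$edges), 4)
  # v-structure children are non-adjacent in the truth graph
  tr <- generate_panel(st$v_structure, 50, seed = 1)$truth
  expect_false(sg_has_edge(tr, "X1", "X2"))
  expect_equal(length(st$seven_hidden$hidden), 2)
  expect_equal(length(setdiff(st$seven_hidden$nodes,
                              st$seven_hidden$hidden)), 7)
})

test_that("hidden nodes are dropped and marked as confounding", {
  spec <- builtin_structures()$seven_hidden
  sim <- generate_panel(spec, 60, seed = 3)
  expect_false(any(spec$hidden %in% series_names(sim$panel)))
  ed <- tidy(sim$truth)
  expect_true(any(ed$type == "bidirected"))
})

test_that("directed F1 scores match hand-computed cases", {
  spec <- builtin_structures()$fork
  truth <- generate_panel(spec, 50, seed = 1)$truth
  expect_equal(f1_directed(truth, truth), 1)

  partial <- summary_graph(truth$nodes)
  partial <- ctmi:::sg_add_edge(partial, "X1", "X2", ctmi:::MARK_TAIL,
                                ctmi:::MARK_ARROW)
  expect_equal(f1_directed(partial, truth), 2 / 3) # TP=1, FN=1

  flipped <- summary_graph(truth$nodes)
  flipped <- ctmi:::sg_add_edge(flipped, "X2", "X1", ctmi:::MARK_TAIL,
                                ctmi:::MARK_ARROW)
  flipped <- ctmi:::sg_add_edge(flipped, "X3", "X1", ctmi:::MARK_TAIL,
                                ctmi:::MARK_ARROW)
  expect_equal(f1_directed(flipped, truth), 0) # all counter-oriented

  # undirected predictions are neither hits nor false alarms
  und <- summary_graph(truth$nodes)
  und <- ctmi:::sg_add_edge(und, "X1", "X2", ctmi:::MARK_TAIL,
                            ctmi:::MARK_TAIL)
  expect_equal(f1_directed(und, truth), 0)

  empty <- summary_graph(c("A", "B"))
  expect_equal(f1_directed(empty, empty), 1)
  expect_error(f1_directed(empty, truth), "same node set")
})

test_that("F1 is invariant under joint node relabeling", {
  spec <- builtin_structures()$diamond
  truth <- generate_panel(spec, 50, seed = 1)$truth
  pred <- summary_graph(truth$nodes)
  pred <- ctmi:::sg_add_edge(pred, "X1", "X2", ctmi:::MARK_TAIL,
                             ctmi:::MARK_ARROW)
  pred <- ctmi:::sg_add_edge(pred, "X4", "X3", ctmi:::MARK_TAIL,
                             ctmi:::MARK_ARROW)
  relabel <- function(g) {
    map <- c(X1 = "n1", X2 = "n2", X3 = "n3", X4 = "n4")
    g$nodes <- unname(map[g$nodes])
    dimnames(g$marks) <- list(g$nodes, g$nodes)
    names(g$self_loops) <- g$nodes
    g
  }
  expect_equal(f1_directed(pred, truth),
               f1_directed(relabel(pred), relabel(truth)))
})

test_that("benchmark reports per-replicate rows and oracle perfection", {
  spec <- builtin_structures()$fork
  b <- run_benchmark("fork", replicates = 2, n_time = 60,
                     cfg = estimator_config(seed = 4),
                     ci_test = dsep_oracle(spec))
  expect_equal(nrow(b), 2)
  expect_true(all(b$f1 == 1))
  gl <- glance(b)
  expect_equal(gl$mean_f1, 1)

  b1 <- run_benchmark("fork", replicates = 1, n_time = 60,
                      cfg = estimator_config(seed = 4),
                      ci_test = dsep_oracle(spec))
  expect_equal(glance(b1)$sd_f1, 0) # single replicate: zero spread
})

test_that("explosive draws are rejected rather than returned", {
  spec <- structure_spec(c("A", "B"), tibble::tibble(from = "A", to = "B"),
                         coef_low = 1, coef_high = 1,
                         nonlinearities = "abs", noise_scale = 10)
  sim <- generate_panel(spec, 50, seed = 1)
  expect_lte(max(abs(as.matrix(sim$panel))), 1e12)
})
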