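test_that("independent variables yield an empty skeleton with empty sepsets", {
  set.seed(201)
  d <- matrix(rnorm(1000), 250, 4, dimnames = list(NULL, letters[1:4]))
  tst <- gauss_ci_test(d)
  sk <- pc_stable_skeleton(tst, learn_config(alpha = 0.01),
                           complete_undirected_graph(letters[1:4]))
  expect_equal(nrow(graph_edges(sk$graph)), 0L)
  expect_length(sk$sepsets, 6L)
  expect_true(all(lengths(sk$sepsets) == 0L))
})

test_that("oracle skeleton of a collider keeps both edges and separates the spouses marginally", {
  d <- mixed_graph(c("xi", "xj", "xk"),
                   directed = rbind(c("xi", "xj"), c("xk", "xj")))
  sk <- pc_stable_skeleton(dsep_ci_test(d), learn_config(),
                           complete_undirected_graph(d$nodes))
  e <- graph_edges(sk$graph)
  expect_setequal(paste(e$from, e$to), c("xi xj", "xj xk"))
  expect_equal(sk$sepsets[["xi|xk"]], character())
  g <- orient_v_structures(sk$graph, sk$sepsets)
  expect_true(g$amat["xi", "xj"] == 1L && g$amat["xj", "xi"] == 0L)
  expect_true(g$amat["xk", "xj"] == 1L && g$amat["xj", "xk"] == 0L)
})

test_that("chain triples stay undirected after v-structure orientation", {
  d <- mixed_graph(c("a", "b", "c"),
                   directed = rbind(c("a", "b"), c("b", "c")))
  sk <- pc_stable_skeleton(dsep_ci_test(d), learn_config(),
                           complete_undirected_graph(d$nodes))
  g <- orient_v_structures(sk$graph, sk$sepsets)
  expect_equal(graph_edges(g)$mark, c("undirected", "undirected"))
})

test_that("oracle v-structure orientation recovers the true colliders on random graphs", {
  set.seed(202)
  for (r in 1:100) {
    d <- random_dag(6, runif(1, 0.2, 0.5))
    sk <- pc_stable_skeleton(dsep_ci_test(d), learn_config(),
                             complete_undirected_graph(d$nodes))
    g <- orient_v_structures(sk$graph, sk$sepsets)
    expect_identical(vs_key_for_test(v_structures(g)),
                     sapply_names(oracle_colliders(d$amat), d$nodes))
  }
})

test_that("pc_stable under oracle tests returns exactly the true CPDAG", {
  set.seed(203)
  for (r in 1:50) {
    d <- random_dag(sample(4:8, 1), runif(1, 0.15, 0.5))
    g <- pc_stable(test = dsep_ci_test(d), cfg = learn_config())
    expect_identical(g$amat, dag_to_cpdag(d)$amat)
  }
})

test_that("independent blocks learn as disconnected components", {
  set.seed(204)
  n <- 500
  a <- rnorm(n); b <- a + rnorm(n, sd = 0.5)
  c_ <- rnorm(n); d_ <- c_ + rnorm(n, sd = 0.5)
  dat <- cbind(a = a, b = b, c = c_, d = d_)
  g <- pc_stable(dat, learn_config(alpha = 0.01))
  e <- graph_edges(g)
  expect_setequal(paste(e$from, e$to), c("a b", "c d"))
})

test_that("smaller alpha never yields more edges", {
  set.seed(205)
  fx <- synthetic_biomarker_dataset(p_per_visit = 4, n_visits = 3,
                                    n_obs = 150, seed = 31)
  g_small <- suppressWarnings(pc_stable(fx$data, learn_config(alpha = 0.02)))
  g_large <- suppressWarnings(pc_stable(fx$data, learn_config(alpha = 0.2)))
  expect_lte(nrow(graph_edges(g_small)), nrow(graph_edges(g_large)))
})

test_that("column permutation leaves PC-stable and COPC-stable output mark-identical", {
  set.seed(206)
  fx <- synthetic_biomarker_dataset(p_per_visit = 4, n_visits = 2,
                                    n_obs = 120, seed = 32)
  perm <- sample(ncol(fx$data))
  dat_p <- fx$data[, perm]
  g1 <- suppressWarnings(pc_stable(fx$data, learn_config(alpha = 0.05)))
  g2 <- suppressWarnings(pc_stable(dat_p, learn_config(alpha = 0.05)))
  expect_identical(g2$amat[g1$nodes, g1$nodes], g1$amat)
  c1 <- suppressWarnings(copc_stable(fx$data, fx$vars,
                                     learn_config(alpha = 0.05, tiered = TRUE)))
  c2 <- suppressWarnings(copc_stable(dat_p, fx$vars,
                                     learn_config(alpha = 0.05, tiered = TRUE)))
  expect_identical(c2$amat, c1$amat)  # copc reorders columns to vars
})

test_that("copc_initial_graph pre-directs cross-tier edges and leaves within-tier undirected", {
  v <- tiered_vars(sprintf("x%d@V%d", rep(1:2, 3), rep(1:3, each = 2)),
                   rep(1:3, each = 2))
  g <- copc_initial_graph(v)
  cnt <- classify_edges(g, v)
  expect_equal(unname(cnt), c(12L, 3L, 0L))
  # single tier: complete undirected
  v1 <- tiered_vars(letters[1:4], rep(1, 4))
  expect_identical(copc_initial_graph(v1)$amat,
                   complete_undirected_graph(letters[1:4])$amat)
  # adding an outcome pre-directs all edges into it
  v2 <- tiered_vars(c(v$names, "y"), c(v$tier, y = 4), outcome = "y")
  g2 <- copc_initial_graph(v2)
  expect_equal(sum(directed_part(g2)[, "y"]), 6L)
  expect_equal(sum(g2$amat["y", ]), 0L)
})

test_that("with a single tier COPC-stable reduces to PC-stable", {
  set.seed(207)
  n <- 200
  x <- rnorm(n); z <- x + rnorm(n); w <- z + rnorm(n)
  dat <- cbind(x = x, z = z, w = w)
  v <- tiered_vars(colnames(dat), rep(1, 3))
  g_pc <- pc_stable(dat, learn_config(alpha = 0.02))
  g_co <- copc_stable(dat, v, learn_config(alpha = 0.02, tiered = TRUE))
  expect_identical(g_co$amat, g_pc$amat)
})

test_that("tiered oracle: COPC recovers the true skeleton with true cross-tier directions", {
  set.seed(208)
  for (r in 1:30) {
    d <- random_tiered_dag(3, 3, edge_prob = 0.3, outcome = (r %% 2 == 0))
    g <- copc_stable(vars = d$vars, cfg = learn_config(tiered = TRUE),
                     test = dsep_ci_test(d))
    expect_identical(adjacency_matrix(g), adjacency_matrix(d))
    tr <- d$vars$tier
    de <- graph_edges(d)
    cross <- de[tr[de$from] != tr[de$to], ]
    for (k in seq_len(nrow(cross)))
      expect_true(g$amat[cross$from[k], cross$to[k]] == 1L &&
                  g$amat[cross$to[k], cross$from[k]] == 0L)
    expect_equal(classify_edges(g, d$vars)[["n_nonchronological"]], 0L)
    expect_true(is_acyclic(g))
  }
})

test_that("COPC tests no more CI relations than PC and never conditions on the outcome", {
  set.seed(209)
  for (r in 1:5) {
    fx <- synthetic_biomarker_dataset(p_per_visit = 4, n_visits = 3,
                                      n_obs = 100, seed = 40 + r)
    g_pc <- suppressWarnings(pc_stable(fx$data, learn_config(alpha = 0.05),
                                       vars = fx$vars))
    g_co <- suppressWarnings(copc_stable(fx$data, fx$vars,
                                         learn_config(alpha = 0.05, tiered = TRUE)))
    expect_lte(attr(g_co, "n_tests"), attr(g_pc, "n_tests"))
    sep_vars <- unlist(attr(g_co, "sepsets"))
    expect_false("Y" %in% sep_vars)
    expect_true(is_acyclic(g_co))
    expect_equal(classify_edges(g_co, fx$vars)[["n_nonchronological"]], 0L)
  }
})

test_that("on tiered oracle problems chronology never de-orients: COPC undirected edges are a subset of PC's", {
  set.seed(210)
  for (r in 1:20) {
    d <- random_tiered_dag(3, 2, edge_prob = 0.35)
    g_pc <- pc_stable(test = dsep_ci_test(d), cfg = learn_config())
    g_co <- copc_stable(vars = d$vars, cfg = learn_config(tiered = TRUE),
                        test = dsep_ci_test(d))
    u_pc <- undirected_part(g_pc)[g_co$nodes, g_co$nodes]
    u_co <- undirected_part(g_co)
    expect_true(all(u_co <= u_pc))
  }
})

test_that("pc_stable refuses tiered configs and propagates non-finite data errors", {
  expect_error(pc_stable(matrix(rnorm(40), 10), learn_config(tiered = TRUE)),
               "copc")
  d <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  d[1, 1] <- Inf
  expect_error(pc_stable(d, learn_config()), "missing or non-finite")
})
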