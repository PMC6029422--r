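test_that("dag_to_cpdag maps Markov-equivalent chains and forks to the undirected chain", {
  for (edges in list(rbind(c("a", "b"), c("b", "c")),     # a -> b -> c
                     rbind(c("b", "a"), c("c", "b")),     # a <- b <- c
                     rbind(c("b", "a"), c("b", "c")))) {  # a <- b -> c
    g <- dag_to_cpdag(mixed_graph(c("a", "b", "c"), directed = edges))
    e <- graph_edges(g)
    expect_equal(e$mark, c("undirected", "undirected"))
    expect_setequal(paste(e$from, e$to), c("a b", "b c"))
  }
})

test_that("v-structures are invariant: a collider maps to itself", {
  coll <- mixed_graph(c("a", "b", "c"),
                      directed = rbind(c("a", "b"), c("c", "b")))
  expect_identical(dag_to_cpdag(coll)$amat, coll$amat)
})

test_that("dag_to_cpdag rejects cyclic and partially undirected input", {
  cyc <- mixed_graph(c("a", "b"), directed = rbind(c("a", "b"), c("b", "a")))
  expect_error(dag_to_cpdag(cyc))
  und <- mixed_graph(c("a", "b"), undirected = rbind(c("a", "b")))
  expect_error(dag_to_cpdag(und), "directed")
})

test_that("dag_to_cpdag agrees with brute-force enumeration on random 6-node DAGs", {
  set.seed(71)
  for (r in 1:100) {
    d <- random_dag(6, runif(1, 0.2, 0.5))
    expect_identical(dag_to_cpdag(d)$amat, oracle_cpdag_amat(d$amat))
  }
})

test_that("every consistent extension of a CPDAG maps back to the same CPDAG", {
  set.seed(72)
  for (r in 1:25) {
    d <- random_dag(6, 0.4)
    cp <- dag_to_cpdag(d)
    for (ext in equivalence_class_dags(cp))
      expect_identical(dag_to_cpdag(ext)$amat, cp$amat)
  }
})

test_that("Meek rule R1 orients away from a collider shield", {
  g <- mixed_graph(c("i", "j", "k"),
                   directed = rbind(c("i", "j")),
                   undirected = rbind(c("j", "k")))
  out <- meek_closure(g)
  expect_equal(graph_edges(out)$mark, c("directed", "directed"))
  expect_true(all(out$amat["j", "k"] == 1L, out$amat["k", "j"] == 0L))
})

test_that("Meek rule R2 closes the triangle chain", {
  g <- mixed_graph(c("i", "j", "k"),
                   directed = rbind(c("i", "k"), c("k", "j")),
                   undirected = rbind(c("i", "j")))
  out <- meek_closure(g)
  expect_true(out$amat["i", "j"] == 1L && out$amat["j", "i"] == 0L)
})

test_that("meek_closure is a fixpoint on fully directed graphs", {
  set.seed(73)
  d <- random_dag(7, 0.4)
  expect_identical(meek_closure(d)$amat, d$amat)
})

test_that("meek_closure commutes with node relabelling", {
  set.seed(74)
  for (r in 1:20) {
    d <- random_dag(6, 0.4)
    pat <- orient_v_structures_pattern(d)
    perm <- sample(d$nodes)
    a <- permute_graph(meek_closure(pat), perm)$amat
    b <- meek_closure(permute_graph(pat, perm))$amat
    expect_identical(a, b[rownames(a), colnames(a)])
  }
})

test_that("shd counts extra plus missing adjacencies; symmetric; zero on self", {
  a <- mixed_graph(c("a", "b", "c", "d"),
                   undirected = rbind(c("a", "b"), c("c", "d")))
  b <- mixed_graph(c("a", "b", "c", "d"),
                   undirected = rbind(c("a", "b"), c("b", "c")))
  expect_equal(shd(a, a), 0L)
  expect_equal(shd(a, b), 2L)   # one extra (c-d), one missing (b-c)
  expect_equal(shd(a, b), shd(b, a))
  empty <- mixed_graph(letters[1:4])
  expect_equal(shd(empty, complete_undirected_graph(letters[1:4])), 6L)
  expect_error(shd(a, mixed_graph(c("x", "y"))), "node")
})

test_that("full-variant shd additionally scores mark mismatches", {
  a <- mixed_graph(c("x", "y"), directed = rbind(c("x", "y")))
  b <- mixed_graph(c("x", "y"), undirected = rbind(c("x", "y")))
  expect_equal(shd(a, b, "paper"), 0L)
  expect_equal(shd(a, b, "full"), 1L)
  expect_equal(shd(a, mixed_graph(c("x", "y"),
                                  directed = rbind(c("y", "x"))), "full"), 1L)
})

test_that("structure_metrics matches a brute-force confusion loop on random graphs", {
  set.seed(75)
  for (r in 1:20) {
    nodes <- paste0("n", 1:8)
    g1 <- random_dag(8, runif(1, 0.1, 0.5), nodes)
    g2 <- random_dag(8, runif(1, 0.1, 0.5), nodes)
    m <- structure_metrics(g1, g2)
    tp <- fp <- tn <- fn <- 0
    for (i in 1:7) for (j in (i + 1):8) {
      e1 <- g1$amat[i, j] + g1$amat[j, i] > 0
      e2 <- g2$amat[i, j] + g2$amat[j, i] > 0
      if (e1 && e2) tp <- tp + 1 else if (e1) fp <- fp + 1
      else if (e2) fn <- fn + 1 else tn <- tn + 1
    }
    expect_equal(m$sensitivity, tp / (tp + fn))
    expect_equal(m$specificity, tn / (tn + fp))
    expect_equal(m$shd, fp + fn)
  }
})

test_that("identical graphs give Se = Sp = 1 and empty estimates give Se = 0, Sp = 1", {
  set.seed(76)
  d <- random_dag(6, 0.5)
  m <- structure_metrics(d, d)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  m2 <- structure_metrics(mixed_graph(d$nodes), d)
  expect_equal(m2$sensitivity, 0)
  expect_equal(m2$specificity, 1)
})

test_that("classify_edges flags backward-in-time and cross-tier undirected edges", {
  v <- tiered_vars(c("x@V1", "y@V1", "z@V2"), c(1, 1, 2))
  back <- mixed_graph(v, directed = rbind(c("z@V2", "x@V1")))
  expect_equal(unname(classify_edges(back, v)), c(1L, 0L, 1L))
  within <- mixed_graph(v, undirected = rbind(c("x@V1", "y@V1")))
  expect_equal(unname(classify_edges(within, v)), c(0L, 1L, 0L))
  cross_und <- mixed_graph(v, undirected = rbind(c("x@V1", "z@V2")))
  expect_equal(unname(classify_edges(cross_und, v)), c(0L, 1L, 1L))
  chrono <- mixed_graph(v, directed = rbind(c("x@V1", "z@V2")))
  expect_equal(unname(classify_edges(chrono, v)), c(1L, 0L, 0L))
})

test_that("aggregate_cpdags applies the 20% retention rule at the boundary", {
  nodes <- c("a", "b", "c")
  with_edge <- mixed_graph(nodes, undirected = rbind(c("a", "b")))
  without <- mixed_graph(nodes)
  in60 <- c(rep(list(with_edge), 60), rep(list(without), 240))
  agg <- aggregate_cpdags(in60, min_freq = 0.20)
  expect_equal(agg$freq["a", "b"], 0.20)
  expect_equal(nrow(graph_edges(agg)), 1L)
  in59 <- c(rep(list(with_edge), 59), rep(list(without), 241))
  expect_equal(nrow(graph_edges(aggregate_cpdags(in59, 0.20))), 0L)
})

test_that("aggregating a single graph returns it with unit frequencies", {
  g <- mixed_graph(c("a", "b", "c"),
                   directed = rbind(c("a", "b")),
                   undirected = rbind(c("b", "c")))
  agg <- aggregate_cpdags(list(g), min_freq = 0.2)
  expect_identical(agg$amat, g$amat)
  expect_equal(unique(edge_freqs_for_test(agg)), 1)
  expect_error(aggregate_cpdags(list()), "empty")
})

test_that("aggregate direction requires strict majority over reverse plus undirected", {
  nodes <- c("a", "b")
  dir_ab <- mixed_graph(nodes, directed = rbind(c("a", "b")))
  dir_ba <- mixed_graph(nodes, directed = rbind(c("b", "a")))
  und <- mixed_graph(nodes, undirected = rbind(c("a", "b")))
  g1 <- aggregate_cpdags(c(rep(list(dir_ab), 3), rep(list(und), 2)), 0.2)
  expect_equal(graph_edges(g1)$mark, "directed")
  g2 <- aggregate_cpdags(c(rep(list(dir_ab), 2), rep(list(und), 2),
                           list(dir_ba)), 0.2)
  expect_equal(graph_edges(g2)$mark, "undirected")
})
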