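# Network construction: pairwise Spearman, split-half edge validation,
# graph assembly, centralities, cliques and module density.

test_that("pairwise Spearman matches rank-formula cases", {
  x <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(5, 4, 3, 2, 1))
  rownames(x) <- paste0("P", 1:5)
  sp <- spearman_pairwise(x)
  expect_equal(sp$rho["a", "b"], 1)
  expect_equal(sp$rho["a", "c"], -1)
  expect_equal(sp$p["a", "b"], 0)

  # 1 - 6 sum(d^2) / (n (n^2 - 1)) for a small permutation
  y <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 3, 4))
  rownames(y) <- paste0("P", 1:4)
  expect_equal(spearman_pairwise(y)$rho["a", "b"], 1 - 6 * 2 / (4 * 15))

  # constant column within the subset: no correlation, never an edge
  z <- cbind(a = 1:6, b = c(2, 2, 2, 2, 2, 2))
  rownames(z) <- paste0("P", 1:6)
  spz <- spearman_pairwise(z)
  expect_true(is.na(spz$rho["a", "b"]))
  expect_true(is.na(spz$p["a", "b"]))
  expect_error(spearman_pairwise(z, subset = 1:3), "at least 4")
})

test_that("duplicated columns always validate; independent columns never do", {
  set.seed(99)
  base <- rexp(300)
  x <- cbind(a = base, b = base, c = rexp(300))
  rownames(x) <- paste0("P", 1:300)
  edges <- validate_edges(x, ccn_control(), seed = 1)
  expect_true("a|b" %in% edge_key_set(edges))
  expect_equal(edges$weight[edges$from == "a" & edges$to == "b"], 1)

  xn <- cbind(g1 = rnorm(1500), g2 = rnorm(1500))
  rownames(xn) <- paste0("P", 1:1500)
  expect_equal(nrow(validate_edges(xn, ccn_control(), seed = 2)), 0L)
})

test_that("edge validation ignores input row order and respects the threshold", {
  coh <- simulate_cohort(cohort_spec(n = 300, groups = data.frame(
    name = c("U1", "U2", "U3", "H1", "H2"),
    block = c("unhealthy", "unhealthy", "unhealthy", "healthy", "healthy"),
    lambda = c(0.9, 0.8, 0.7, 0.9, 0.8), sigma = 1, pi = 0, mu = 2)),
    seed = 4)
  x <- coh$intake
  e1 <- validate_edges(x, ccn_control(), seed = 10)
  perm <- sample(nrow(x))
  e2 <- validate_edges(x[perm, ], ccn_control(), seed = 10)
  expect_equal(e1, e2)

  # edge set shrinks monotonically in the soft threshold (same splits)
  lo <- validate_edges(x, ccn_control(r_threshold = 0.1), seed = 10)
  hi <- validate_edges(x, ccn_control(r_threshold = 0.35), seed = 10)
  expect_true(all(edge_key_set(hi) %in% edge_key_set(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("graph assembly keeps isolated nodes and checks endpoints", {
  scores <- c(a = 10L, b = 20L, c = 5L)
  g0 <- build_graph(data.frame(from = character(0), to = character(0),
                               weight = numeric(0)), scores)
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 0)

  g1 <- build_graph(data.frame(from = "a", to = "b", weight = 0.5), scores)
  deg <- igraph::degree(g1)
  expect_equal(unname(deg[c("a", "b", "c")]), c(1, 1, 0))
  expect_equal(sum(deg), 2 * igraph::ecount(g1))
  expect_error(build_graph(data.frame(from = "a", to = "z", weight = 0.5),
                           scores), "missing from scores.*z")
})

test_that("centralities match hand values on canonical small graphs", {
  # path a-b-c
  gp <- graph_from_edges(c("a", "b", "c"),
                         data.frame(from = c("a", "b"), to = c("b", "c")))
  cp <- centralities(gp)
  expect_equal(cp$degree[cp$group == "b"], 2L)
  expect_equal(cp$betweenness[cp$group == "b"], 1)
  expect_equal(cp$closeness[cp$group == "b"], 1)

  # isolated node scores zero on all three
  gi <- graph_from_edges(c("a", "b", "z"),
                         data.frame(from = "a", to = "b"))
  ci <- centralities(gi)
  expect_equal(unlist(ci[ci$group == "z", c("degree", "betweenness", "closeness")],
                      use.names = FALSE), c(0, 0, 0))

  # 4-cycle: betweenness equal on all nodes, value from path enumeration
  cyc <- data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a"))
  gc4 <- graph_from_edges(letters[1:4], cyc)
  cc4 <- centralities(gc4)
  A <- oracle_adj(letters[1:4], cyc)
  expect_equal(cc4$betweenness, oracle_betweenness(A))
  expect_equal(length(unique(round(cc4$betweenness, 12))), 1L)
})

test_that("centralities agree with path-enumeration oracles on random graphs", {
  set.seed(17)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    edges <- random_edges(n, 0.45)
    if (!nrow(edges)) next
    g <- graph_from_edges(letters[seq_len(n)], edges)
    A <- oracle_adj(letters[seq_len(n)], edges)
    cg <- centralities(g)
    expect_equal(cg$betweenness, oracle_betweenness(A), tolerance = 1e-12)
    expect_equal(cg$closeness, oracle_closeness(A), tolerance = 1e-12)
    expect_equal(cg$degree, unname(rowSums(A)))
  }
})

test_that("maximal cliques match subset enumeration", {
  k4 <- data.frame(from = c("a", "a", "a", "b", "b", "c"),
                   to = c("b", "c", "d", "c", "d", "d"))
  g <- graph_from_edges(letters[1:4], k4)
  expect_equal(ccn_cliques(g, 2), list(c("a", "b", "c", "d")))

  pend <- rbind(k4, data.frame(from = "d", to = "e"))
  gp <- graph_from_edges(letters[1:5], pend)
  expect_equal(ccn_cliques(gp, 2),
               list(c("a", "b", "c", "d"), c("d", "e")))

  set.seed(23)
  for (i in 1:5) {
    edges <- random_edges(10, 0.5)
    g10 <- graph_from_edges(letters[1:10], edges)
    A <- oracle_adj(letters[1:10], edges)
    expect_identical(ccn_cliques(g10, 2), oracle_cliques(A, 2))
    expect_identical(ccn_cliques(g10, 3), oracle_cliques(A, 3))
  }
})

test_that("module density is connections per node", {
  k4 <- data.frame(from = c("a", "a", "a", "b", "b", "c"),
                   to = c("b", "c", "d", "c", "d", "d"))
  g <- graph_from_edges(letters[1:5], k4)
  expect_equal(module_density(g, letters[1:4]), 6 / 4)
  expect_equal(module_density(g, c("a", "b")), 1 / 2)
  expect_error(module_density(g, character(0)), "empty")
  expect_error(module_density(g, c("a", "q")), "not in graph")
})

test_that("the ccn fitter returns a coherent object", {
  coh <- simulate_cohort(cohort_spec(n = 250, groups = data.frame(
    name = c("U1", "U2", "U3", "H1", "H2", "H3", "N1"),
    block = c(rep("unhealthy", 3), rep("healthy", 3), "neutral"),
    lambda = c(0.9, 0.85, 0.8, 0.9, 0.85, 0.8, 0), sigma = 1, pi = 0, mu = 2)),
    seed = 12)
  fit <- ccn(coh$intake, seed = 12)
  expect_s3_class(fit, "ccn")
  expect_equal(sum(igraph::degree(fit$graph)), 2 * nrow(fit$edges))
  expect_true(all(fit$edges$weight > fit$control$r_threshold))
  expect_false("N1" %in% names(fit$partition))
  s <- summary(fit)
  expect_s3_class(s, "summary.ccn")
  expect_equal(s$n_edges, nrow(fit$edges))
  # deterministic refit
  fit2 <- ccn(coh$intake, seed = 12)
  expect_equal(fit$edges, fit2$edges)
  expect_identical(fit$partition, fit2$partition)
})
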