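# Community detection, modularity, membership assignment, steatosis grades
# and member comparison.

two_triangles <- function() {
  graph_from_edges(letters[1:6], data.frame(
    from = c("a", "a", "b", "d", "d", "e"),
    to = c("b", "c", "c", "e", "f", "f")))
}

test_that("label propagation resolves disconnected cliques exactly", {
  g <- two_triangles()
  for (seed in 1:10) {
    p <- label_propagation(g, seed = seed)
    expect_equal(unname(p[c("a", "b", "c")]), rep(p[["a"]], 3))
    expect_equal(unname(p[c("d", "e", "f")]), rep(p[["d"]], 3))
    expect_false(p[["a"]] == p[["d"]])
  }
  # complete graph: a single community
  k5 <- t(combn(letters[1:5], 2))
  gk <- graph_from_edges(letters[1:5],
                         data.frame(from = k5[, 1], to = k5[, 2]))
  expect_equal(length(unique(label_propagation(gk, seed = 1))), 1L)
  # edgeless graph is an error
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  expect_error(label_propagation(g0), "edgeless")
})

test_that("two cliques joined by a bridge usually split at the bridge", {
  k5a <- t(combn(letters[1:5], 2))
  k5b <- t(combn(letters[6:10], 2))
  edges <- data.frame(from = c(k5a[, 1], k5b[, 1], "e"),
                      to = c(k5a[, 2], k5b[, 2], "f"))
  g <- graph_from_edges(letters[1:10], edges)
  hits <- 0
  for (seed in 1:100) {
    p <- label_propagation(g, seed = seed)
    two_k5 <- length(unique(p)) == 2 &&
      length(unique(p[letters[1:5]])) == 1 &&
      length(unique(p[letters[6:10]])) == 1
    hits <- hits + two_k5
  }
  expect_gt(hits, 50)
  # and consensus settles on that majority answer
  cp <- consensus_partition(g, n_runs = 50, seed = 1)
  expect_equal(length(unique(cp)), 2L)
  expect_equal(length(unique(cp[letters[1:5]])), 1L)
})

test_that("consensus on disconnected triangles is unanimous and canonical", {
  g <- two_triangles()
  cp <- consensus_partition(g, n_runs = 50, seed = 7)
  expect_equal(attr(cp, "frequency"), 50L)
  expect_equal(unname(cp[order(names(cp))]), c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("canonical form is invariant to module relabeling", {
  set.seed(41)
  memb <- setNames(sample(1:3, 8, replace = TRUE), letters[1:8])
  can <- ccnet:::canonical_partition(memb)
  for (i in 1:10) {
    relab <- sample(100:200, 3)[memb]
    names(relab) <- names(memb)
    relab <- relab[sample(8)]
    expect_identical(ccnet:::canonical_partition(relab), can)
  }
})

test_that("modularity matches hand values and the double-sum oracle", {
  g <- two_triangles()
  # one all-in module: Q = 0
  p1 <- setNames(rep(1L, 6), letters[1:6])
  expect_equal(ccn_modularity(g, p1), 0)
  # the two-triangle partition: Q = 0.5
  p2 <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), letters[1:6])
  expect_equal(ccn_modularity(g, p2), 0.5)

  set.seed(53)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    edges <- random_edges(n, 0.5)
    if (!nrow(edges)) next
    g <- graph_from_edges(letters[seq_len(n)], edges)
    A <- oracle_adj(letters[seq_len(n)], edges)
    memb <- setNames(sample(1:3, n, replace = TRUE), letters[seq_len(n)])
    q <- ccn_modularity(g, memb)
    expect_equal(q, oracle_modularity(A, memb[rownames(A)]), tolerance = 1e-12)
    # igraph's implementation is an independent cross-check
    expect_equal(q, igraph::modularity(g, memb[igraph::V(g)$name]),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric membership reproduces enumeration probabilities", {
  part <- setNames(c(rep(1L, 5), rep(2L, 5)), paste0("g", 1:10))
  mk_row <- function(consumed) {
    b <- matrix(0L, 1, 10, dimnames = list("P1", paste0("g", 1:10)))
    b[1, consumed] <- 1L
    b
  }
  # 4 consumed groups all inside module 1: P(X >= 4) = 5/210
  m <- hypergeometric_membership(mk_row(paste0("g", 1:4)), part, 0.1)
  expect_equal(m$p_1, 5 / 210, tolerance = 1e-12)
  expect_equal(m$label, "1")
  # 4 consumed, 2 inside: P(X >= 2) = 155/210, not a member
  m2 <- hypergeometric_membership(mk_row(paste0("g", c(1, 2, 6, 7))), part, 0.1)
  expect_equal(m2$p_1, 155 / 210, tolerance = 1e-12)
  expect_equal(m2$label, "other")
  # consumes nothing: p = 1 for both modules, label other
  m0 <- hypergeometric_membership(mk_row(character(0)), part, 0.1)
  expect_equal(c(m0$p_1, m0$p_2), c(1, 1))
  expect_equal(m0$label, "other")
})

test_that("membership p-values match the pmf oracle and decrease in k", {
  set.seed(61)
  N <- 12; K <- 5
  part <- setNames(c(rep(1L, K), rep(2L, N - K)), paste0("g", 1:N))
  for (i in 1:20) {
    consumed <- sample(N, sample(0:N, 1))
    b <- matrix(0L, 1, N, dimnames = list("P1", paste0("g", 1:N)))
    b[1, consumed] <- 1L
    m <- hypergeometric_membership(b, part, 0.1)
    k <- sum(consumed <= K)
    n <- length(consumed)
    expect_equal(m$p_1, oracle_hyper_upper(k, N, K, n), tolerance = 1e-12)
    expect_equal(m$p_2, oracle_hyper_upper(n - k, N, N - K, n),
                 tolerance = 1e-12)
  }
  # monotone: for fixed n, the p-value never increases as k grows
  n <- 6
  ps <- vapply(0:n, function(k) oracle_hyper_upper(k, N, K, n), numeric(1))
  b_ps <- vapply(0:n, function(k) {
    b <- matrix(0L, 1, N, dimnames = list("P1", paste0("g", 1:N)))
    b[1, c(seq_len(k), K + seq_len(n - k))] <- 1L
    hypergeometric_membership(b, part, 0.1)$p_1
  }, numeric(1))
  expect_equal(b_ps, ps, tolerance = 1e-12)
  expect_true(all(diff(b_ps) <= 1e-12))
})

test_that("every participant gets exactly one of the three labels", {
  coh <- simulate_cohort(default_cohort_spec(), seed = 77)
  fit <- ccn(coh$intake, seed = 77)
  m <- hypergeometric_membership(fit$binarized, fit$partition, 0.1)
  expect_equal(nrow(m), 1500)
  expect_true(all(m$label %in% c("1", "2", "other")))
  both_or_none <- (m$p_1 < 0.1) == (m$p_2 < 0.1)
  expect_identical(m$label == "other", both_or_none)
})

test_that("adjusted Rand agrees with the mclust reference implementation", {
  set.seed(47)
  for (i in 1:10) {
    a <- sample(1:3, 25, replace = TRUE)
    b <- sample(1:4, 25, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})

test_that("CAP steatosis grading honors the boundary conventions", {
  expect_equal(as.character(cap_grade(c(100, 237.9, 238, 250, 259.9, 260,
                                        292.9, 293, 300))),
               c("S0", "S0", "S1", "S1", "S1", "S2", "S2", "S3", "S3"))
  grades <- cap_grade(seq(150, 350, by = 5))
  expect_true(all(diff(as.integer(grades)) >= 0))
  expect_error(cap_grade(c(250, 0)), "positive")
  expect_error(cap_grade(-3), "positive")
})

test_that("member comparison reproduces the pooled t-test closed form", {
  mk <- function(vals1, vals2) {
    n1 <- length(vals1); n2 <- length(vals2)
    membership <- data.frame(
      id = paste0("P", seq_len(n1 + n2)),
      label = rep(c("unhealthy", "healthy"), c(n1, n2)),
      stringsAsFactors = FALSE)
    covariates <- data.frame(
      id = membership$id, age = c(vals1, vals2),
      sex = rep(c("male", "female"), length.out = n1 + n2),
      bmi = 25, energy = 2000, cap = 250, stringsAsFactors = FALSE)
    compare_members(membership, validate_covariates(covariates))
  }
  out <- mk(c(1, 2, 3), c(4, 5, 6))
  # pooled SD = 1, t = (2 - 5) / sqrt(2/3), df = 4
  t_exp <- -3 / sqrt(2 / 3)
  expect_equal(out$p[out$variable == "Age (years)"],
               2 * pt(-abs(t_exp), df = 4), tolerance = 1e-12)
  # identical distributions: p = 1 for the numeric comparison
  out2 <- mk(c(1, 2, 3), c(1, 2, 3))
  expect_equal(out2$p[out2$variable == "Age (years)"], 1)
  expect_error(mk(1, c(2, 3)), "at least 2")
})
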