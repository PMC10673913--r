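# Community detection, modularity, participant module membership, steatosis
# grading and member comparisons.

# Canonical form of a partition: nodes sorted by name, module ids renumbered
# 1..k in order of first appearance over the sorted names. Any relabeling of
# the same grouping maps to the same canonical vector.
canonical_partition <- function(memb) {
  memb <- memb[order(names(memb))]
  ids <- unique(unname(memb))
  out <- match(memb, ids)
  names(out) <- names(memb)
  out
}

partition_key <- function(p) {
  paste(names(p), p, sep = ":", collapse = ";")
}

lp_once <- function(g) {
  keep <- which(igraph::degree(g) > 0)
  sub <- igraph::induced_subgraph(g, keep)
  cl <- igraph::cluster_label_prop(sub)
  canonical_partition(stats::setNames(as.integer(igraph::membership(cl)),
                                      igraph::V(sub)$name))
}

#' Label-propagation community detection
#'
#' One run of asynchronous label propagation: every node starts with its own
#' label and repeatedly adopts the most frequent label among its neighbors
#' (ties broken at random) until each node's label is modal in its
#' neighborhood. Isolated nodes are excluded from the partition. Distinct
#' runs can return different partitions; see [consensus_partition()].
#'
#' @param x a `ccn` fit or igraph graph with at least one edge.
#' @param seed integer seed (optional; omitted = use the current RNG stream).
#' @return named integer vector of canonical module ids over non-isolated
#'   nodes.
#' @export
label_propagation <- function(x, seed = NULL) {
  g <- as_ccn_graph(x)
  if (igraph::ecount(g) == 0)
    stop("edgeless graph: no communities defined")
  if (!is.null(seed)) {
    restore <- local_seed(seed)
    on.exit(restore(), add = TRUE)
  }
  lp_once(g)
}

#' Consensus partition over label-propagation restarts
#'
#' Runs label propagation `n_runs` times from different random initial
#' conditions, canonicalizes every resulting partition and returns the most
#' frequent one. Frequency ties are broken by higher modularity, then by
#' lexicographically smallest canonical form, so the result is deterministic
#' given the seed.
#'
#' @param x a `ccn` fit or igraph graph with at least one edge.
#' @param n_runs number of restarts (default 50).
#' @param seed integer seed.
#' @return named integer vector of canonical module ids, with attributes
#'   `frequency` (runs returning it) and `n_runs`.
#' @export
consensus_partition <- function(x, n_runs = 50L, seed = 1L) {
  g <- as_ccn_graph(x)
  if (igraph::ecount(g) == 0)
    stop("edgeless graph: no communities defined")
  stopifnot(n_runs >= 1)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) runs[[i]] <- lp_once(g)
  keys <- vapply(runs, partition_key, character(1))
  tab <- table(keys)
  best <- names(tab)[tab == max(tab)]
  if (length(best) > 1) {
    cand <- runs[match(best, keys)]
    q <- vapply(cand, function(p) ccn_modularity(g, p), numeric(1))
    best <- best[q == max(q)]
    best <- sort(best)[1]
  }
  out <- runs[[match(best, keys)]]
  attr(out, "frequency") <- as.integer(tab[best])
  attr(out, "n_runs") <- as.integer(n_runs)
  out
}

#' Modularity of a partition
#'
#' Q = sum over modules c of (e_cc - a_c^2) on the unweighted topology,
#' where e_cc is the fraction of edges inside module c and a_c the fraction
#' of edge endpoints in c. Lies in \[-1, 1\]; positive values indicate
#' modular structure. Nodes absent from the partition must be isolated.
#'
#' @param x a `ccn` fit or igraph graph.
#' @param partition named module-id vector (e.g. from
#'   [consensus_partition()]).
#' @return the modularity score.
#' @export
ccn_modularity <- function(x, partition) {
  g <- as_ccn_graph(x)
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  el <- igraph::as_edgelist(g)
  c1 <- partition[el[, 1]]
  c2 <- partition[el[, 2]]
  if (anyNA(c1) || anyNA(c2))
    stop("partition must cover every non-isolated node")
  mods <- unique(c(c1, c2))
  q <- 0
  for (cc in mods) {
    inside <- sum(c1 == cc & c2 == cc) / m
    ends <- (sum(c1 == cc) + sum(c2 == cc)) / (2 * m)
    q <- q + inside - ends^2
  }
  q
}

#' Assign participants to modules by hypergeometric enrichment
#'
#' For each participant and each of the two modules: with N the number of
#' module-labeled food groups, K the module size, n the number of labeled
#' groups the participant consumes (binarized indicator 1) and k the number
#' of those inside the module, the upper-tail probability P(X >= k) of
#' Hypergeometric(N, K, n) measures over-representation. A participant is a
#' member of a module when its p-value is below `p_threshold`; participants
#' enriched in both modules or in neither are labeled "other". A participant
#' consuming no labeled group has p = 1 for both modules.
#'
#' @param binarized 0/1 matrix from [binarize()].
#' @param partition named module-id vector with exactly two modules.
#' @param p_threshold membership criterion (default 0.1).
#' @return data frame with columns `id`, `label` (module id as character, or
#'   "other") and one p-value column per module (`p_1`, `p_2`).
#' @export
hypergeometric_membership <- function(binarized, partition, p_threshold = 0.1) {
  mods <- sort(unique(unname(partition)))
  if (length(mods) != 2)
    stop("membership assignment requires exactly two modules")
  labeled <- names(partition)
  missing_groups <- setdiff(labeled, colnames(binarized))
  if (length(missing_groups))
    stop("binarized matrix lacks groups: ", paste(missing_groups, collapse = ", "))
  bl <- binarized[, labeled, drop = FALSE]
  N <- length(labeled)
  nvec <- rowSums(bl)
  pmat <- vapply(mods, function(m) {
    K <- sum(partition == m)
    k <- rowSums(bl[, names(partition)[partition == m], drop = FALSE])
    stats::phyper(k - 1, K, N - K, nvec, lower.tail = FALSE)
  }, numeric(nrow(bl)))
  pmat <- matrix(pmat, nrow = nrow(bl), ncol = length(mods))
  member <- pmat < p_threshold
  label <- ifelse(rowSums(member) == 1,
                  as.character(mods[apply(member, 1, which.max)]),
                  "other")
  out <- data.frame(id = rownames(binarized), label = label,
                    stringsAsFactors = FALSE)
  for (j in seq_along(mods)) out[[paste0("p_", mods[j])]] <- pmat[, j]
  rownames(out) <- NULL
  out
}

#' Name the modules healthy/unhealthy from member CAP scores
#'
#' Relabels the two module ids so the module whose members have the higher
#' mean CAP score becomes "unhealthy" and the other "healthy".
#'
#' @param membership data frame from [hypergeometric_membership()].
#' @param covariates covariate table with `id` and `cap`.
#' @return list with `membership` (labels renamed; p-value columns renamed
#'   `p_unhealthy`, `p_healthy`) and `module_names` (named map from module id
#'   to name).
#' @export
orient_modules <- function(membership, covariates) {
  mods <- setdiff(unique(membership$label), "other")
  if (length(mods) != 2) stop("expected members of exactly two modules")
  cap <- covariates$cap[match(membership$id, covariates$id)]
  means <- vapply(mods, function(m) mean(cap[membership$label == m]),
                  numeric(1))
  unhealthy <- mods[which.max(means)]
  map <- stats::setNames(ifelse(mods == unhealthy, "unhealthy", "healthy"),
                         mods)
  membership$label <- ifelse(membership$label == "other", "other",
                             unname(map[membership$label]))
  pcols <- grep("^p_", names(membership))
  names(membership)[pcols] <- paste0("p_", map[sub("^p_", "",
                                                   names(membership)[pcols])])
  list(membership = membership, module_names = map)
}

#' Steatosis grade from CAP score
#'
#' Controlled attenuation parameter cutoffs 238, 260 and 293 dB/m define
#' grades S0 (< 238, normal liver), S1 (238-260, mild), S2 (260-293,
#' moderate) and S3 (>= 293, severe). Intervals are closed on the left
#' except S0, so 238 grades S1 and 293 grades S3.
#'
#' @param cap numeric vector of CAP scores (dB/m), all positive.
#' @param cutoffs the three grade boundaries.
#' @return ordered factor with levels S0 < S1 < S2 < S3.
#' @export
cap_grade <- function(cap, cutoffs = c(238, 260, 293)) {
  if (any(!is.finite(cap)) || any(cap <= 0))
    stop("CAP scores must be positive")
  cut(cap, breaks = c(0, cutoffs, Inf), right = FALSE,
      labels = c("S0", "S1", "S2", "S3"), ordered_result = TRUE)
}

#' Compare covariates between unhealthy- and healthy-module members
#'
#' Members labeled "other" are excluded. Age, energy, BMI and CAP are
#' compared by two-sample t-tests (pooled variance by default); sex and the
#' steatosis-grade distribution by chi-square tests.
#'
#' @param membership oriented membership data frame (labels "unhealthy",
#'   "healthy", "other"), e.g. from [orient_modules()].
#' @param covariates covariate table.
#' @param labels the two member labels to compare (first vs second).
#' @param var_equal pooled-variance t-test when TRUE (default), Welch
#'   otherwise.
#' @param cap_cutoffs steatosis cutoffs for the grade comparison.
#' @return data frame with one row per variable: group means/SDs (or counts
#'   and percentages for categorical rows) and the p-value.
#' @export
compare_members <- function(membership, covariates,
                            labels = c("unhealthy", "healthy"),
                            var_equal = TRUE,
                            cap_cutoffs = c(238, 260, 293)) {
  cov <- covariates[match(membership$id, covariates$id), , drop = FALSE]
  g1 <- membership$label == labels[1]
  g2 <- membership$label == labels[2]
  if (sum(g1) < 2 || sum(g2) < 2)
    stop("need at least 2 participants per member group")
  num_row <- function(var, pretty) {
    x1 <- cov[[var]][g1]; x2 <- cov[[var]][g2]
    p <- if (stats::sd(x1) == 0 && stats::sd(x2) == 0 && mean(x1) == mean(x2)) 1
    else stats::t.test(x1, x2, var.equal = var_equal)$p.value
    data.frame(variable = pretty,
               mean_1 = mean(x1), sd_1 = stats::sd(x1),
               mean_2 = mean(x2), sd_2 = stats::sd(x2),
               n_1 = NA_real_, pct_1 = NA_real_,
               n_2 = NA_real_, pct_2 = NA_real_,
               p = p, stringsAsFactors = FALSE)
  }
  rows <- list(
    num_row("age", "Age (years)"),
    num_row("energy", "Energy (kcal/d)"),
    num_row("bmi", "BMI (kg/m2)"),
    num_row("cap", "CAP score (dB/m)"))
  # sex: count/percent female per group, chi-square on the 2x2 table
  sex_tab <- table(factor(membership$label[g1 | g2], levels = labels),
                   cov$sex[g1 | g2])
  p_sex <- suppressWarnings(stats::chisq.test(sex_tab, correct = FALSE)$p.value)
  rows <- c(rows, list(data.frame(
    variable = "Sex (female)",
    mean_1 = NA_real_, sd_1 = NA_real_, mean_2 = NA_real_, sd_2 = NA_real_,
    n_1 = sex_tab[1, "female"], pct_1 = 100 * sex_tab[1, "female"] / sum(g1),
    n_2 = sex_tab[2, "female"], pct_2 = 100 * sex_tab[2, "female"] / sum(g2),
    p = p_sex, stringsAsFactors = FALSE)))
  grade <- cap_grade(cov$cap, cap_cutoffs)
  grade_tab <- table(factor(membership$label[g1 | g2], levels = labels),
                     grade[g1 | g2])
  p_grade <- suppressWarnings(stats::chisq.test(grade_tab)$p.value)
  for (gl in levels(grade)) {
    rows <- c(rows, list(data.frame(
      variable = paste("Steatosis", gl),
      mean_1 = NA_real_, sd_1 = NA_real_, mean_2 = NA_real_, sd_2 = NA_real_,
      n_1 = grade_tab[1, gl], pct_1 = 100 * grade_tab[1, gl] / sum(g1),
      n_2 = grade_tab[2, gl], pct_2 = 100 * grade_tab[2, gl] / sum(g2),
      p = p_grade, stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  names(out) <- sub("_1$", paste0("_", labels[1]), names(out))
  names(out) <- sub("_2$", paste0("_", labels[2]), names(out))
  attr(out, "group_sizes") <- stats::setNames(c(sum(g1), sum(g2)), labels)
  out
}
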