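# Co-consumption network construction: split-half resampling validation of
# pairwise Spearman correlations, graph assembly and descriptive metrics.

#' Control parameters for CCN construction
#'
#' @param n_repeats number of random split-half repeats (default 100). An
#'   edge must be significant in both halves of every repeat.
#' @param split_fraction fraction of participants in the test half.
#' @param alpha per-test two-sided significance level.
#' @param r_threshold soft threshold: the mean test-half correlation must
#'   exceed this for a pair to be connected (default 0.2).
#' @param require_positive require both half correlations positive in every
#'   repeat (default TRUE; the network keeps only positive co-consumption).
#' @param quantile_type quantile type for the binarization rule.
#' @param n_runs label-propagation restarts for the consensus partition.
#' @param p_threshold hypergeometric membership p-value threshold.
#' @param min_clique minimum clique size for module-related clique tests.
#' @param fdr_level FDR level for clique association calls.
#' @param age_cutoffs two age cutoffs (years) defining the three age strata.
#' @param cap_cutoffs three CAP cutoffs (dB/m) defining steatosis grades
#'   S0-S3; the first and third also define the normal/NAFLD strata.
#' @return object of class `ccn_control`.
#' @export
ccn_control <- function(n_repeats = 100L, split_fraction = 0.5, alpha = 0.05,
                        r_threshold = 0.2, require_positive = TRUE,
                        quantile_type = 7, n_runs = 50L, p_threshold = 0.1,
                        min_clique = 4L, fdr_level = 0.05,
                        age_cutoffs = c(30, 50),
                        cap_cutoffs = c(238, 260, 293)) {
  stopifnot(n_repeats >= 1, split_fraction > 0, split_fraction < 1,
            alpha > 0, alpha < 1, r_threshold >= 0,
            n_runs >= 1, p_threshold > 0, p_threshold < 1,
            min_clique >= 2, fdr_level > 0, fdr_level < 1,
            length(age_cutoffs) == 2, diff(age_cutoffs) > 0,
            length(cap_cutoffs) == 3, all(diff(cap_cutoffs) > 0))
  out <- list(n_repeats = as.integer(n_repeats),
              split_fraction = split_fraction, alpha = alpha,
              r_threshold = r_threshold, require_positive = require_positive,
              quantile_type = quantile_type, n_runs = as.integer(n_runs),
              p_threshold = p_threshold, min_clique = as.integer(min_clique),
              fdr_level = fdr_level, age_cutoffs = age_cutoffs,
              cap_cutoffs = cap_cutoffs)
  class(out) <- "ccn_control"
  out
}

#' Pairwise Spearman correlations with two-sided p-values
#'
#' Rank correlation with average (mid) ranks for ties; p-values from the
#' t approximation on n - 2 degrees of freedom. Pairs involving a constant
#' column get NA correlation and NA p (never an edge).
#'
#' @param x intake matrix.
#' @param subset optional row indices or participant IDs restricting the
#'   computation (at least 4 participants).
#' @return list with symmetric matrices `rho` and `p` (diagonal NA).
#' @export
spearman_pairwise <- function(x, subset = NULL) {
  x <- check_numeric_matrix(x)
  if (!is.null(subset)) x <- x[subset, , drop = FALSE]
  n <- nrow(x)
  if (n < 4) stop("need at least 4 participants for correlation")
  r <- apply(x, 2, rank)
  sds <- apply(r, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(r))
  rho[sds == 0, ] <- NA
  rho[, sds == 0] <- NA
  diag(rho) <- NA
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[abs(rho) >= 1 - 1e-12] <- 0
  p[is.na(rho)] <- NA
  diag(p) <- NA
  list(rho = rho, p = p, n = n)
}

#' Resampling-validated co-consumption edges
#'
#' Participants are repeatedly split at random into a test and a validation
#' half. A food-group pair is connected iff in every repeat its Spearman
#' correlation is significant at `alpha` in both halves (and positive in
#' both, when `require_positive`), and the mean of the test-half correlations
#' over all repeats exceeds `r_threshold`. The edge weight is that mean.
#'
#' Rows are internally ordered by participant ID before splitting, so the
#' result depends only on the seed and the set of participants, not on the
#' row order of the input.
#'
#' @param x intake matrix.
#' @param control a [ccn_control()].
#' @param seed integer seed for the split sequence.
#' @return data frame with columns `from`, `to`, `weight` (mean test rho).
#' @export
validate_edges <- function(x, control = ccn_control(), seed = 1L) {
  x <- check_numeric_matrix(x)
  x <- x[order(rownames(x)), , drop = FALSE]
  n <- nrow(x)
  n_test <- floor(control$split_fraction * n)
  if (n_test < 4 || n - n_test < 4)
    stop("too few participants (", n, ") for split-half validation")
  G <- ncol(x)
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  alive <- matrix(TRUE, G, G)
  sum_rho <- matrix(0, G, G)
  for (r in seq_len(control$n_repeats)) {
    idx <- sample.int(n)
    test <- idx[seq_len(n_test)]
    val <- idx[-seq_len(n_test)]
    st <- spearman_pairwise(x, test)
    sv <- spearman_pairwise(x, val)
    ok <- !is.na(st$p) & !is.na(sv$p) &
      st$p < control$alpha & sv$p < control$alpha
    if (control$require_positive)
      ok <- ok & st$rho > 0 & sv$rho > 0
    ok[is.na(ok)] <- FALSE
    alive <- alive & ok
    rho_t <- st$rho
    rho_t[is.na(rho_t)] <- 0
    sum_rho <- sum_rho + rho_t
  }
  mean_rho <- sum_rho / control$n_repeats
  keep <- alive & mean_rho > control$r_threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  ij <- which(keep, arr.ind = TRUE)
  out <- data.frame(from = colnames(x)[ij[, 1]],
                    to = colnames(x)[ij[, 2]],
                    weight = mean_rho[ij],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Assemble a CCN graph from validated edges and node weights
#'
#' @param edges data frame from [validate_edges()].
#' @param scores named consumption-score vector covering every food group
#'   (isolated groups are retained as weight-carrying isolated nodes).
#' @return an igraph undirected graph with vertex attribute `weight`
#'   (consumption score) and edge attribute `weight` (mean test correlation).
#' @export
build_graph <- function(edges, scores) {
  if (is.null(names(scores))) stop("scores must be a named vector")
  missing_nodes <- setdiff(unique(c(edges$from, edges$to)), names(scores))
  if (length(missing_nodes))
    stop("edge endpoints missing from scores: ",
         paste(missing_nodes, collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = data.frame(name = names(scores), weight = as.numeric(scores),
                          stringsAsFactors = FALSE))
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Fit a co-consumption network
#'
#' The main fitting function: binarizes the intake matrix by the quartile
#' consumer rule, computes consumption scores (node weights), validates
#' edges by split-half resampling, assembles the graph and partitions its
#' connected part into modules by consensus label propagation.
#'
#' @param intake participant-by-food-group intake matrix (g/day).
#' @param control a [ccn_control()].
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @return object of class `ccn` with components `graph` (igraph), `edges`,
#'   `score`, `binarized`, `partition` (named module ids over non-isolated
#'   nodes, NULL if the graph is edgeless), `modularity`, `n`, `groups`,
#'   `control`, `seed`.
#' @examples
#' coh <- simulate_cohort(default_cohort_spec(), seed = 7)
#' \donttest{
#' fit <- ccn(coh$intake, seed = 7)
#' print(fit)
#' }
#' @export
ccn <- function(intake, control = ccn_control(), seed = 1L) {
  intake <- validate_intake(intake)
  bin <- binarize(intake, type = control$quantile_type)
  score <- consumption_score(bin)
  edges <- validate_edges(intake, control, seed = derive_seed(seed, "edges"))
  graph <- build_graph(edges, score)
  partition <- NULL
  modularity <- NA_real_
  if (nrow(edges) > 0) {
    partition <- consensus_partition(graph, n_runs = control$n_runs,
                                     seed = derive_seed(seed, "communities"))
    modularity <- ccn_modularity(graph, partition)
  }
  out <- list(graph = graph, edges = edges, score = score, binarized = bin,
              partition = partition, modularity = modularity,
              n = nrow(intake), groups = colnames(intake),
              control = control, seed = as.integer(seed),
              call = match.call())
  class(out) <- "ccn"
  out
}

#' @export
print.ccn <- function(x, ...) {
  iso <- sum(igraph::degree(x$graph) == 0)
  cat("Co-consumption network:", length(x$groups), "food groups,",
      nrow(x$edges), "validated edges,", iso, "isolated\n")
  cat("  participants:", x$n,
      " threshold: mean rho >", x$control$r_threshold,
      "over", x$control$n_repeats, "split-half repeats\n")
  if (!is.null(x$partition)) {
    sizes <- table(x$partition)
    cat("  modules:", paste(sprintf("M%s (%d nodes)", names(sizes), sizes),
                            collapse = ", "),
        " modularity:", round(x$modularity, 3), "\n")
  }
  invisible(x)
}

#' @export
summary.ccn <- function(object, ...) {
  cent <- centralities(object)
  hub <- cent$group[which.max(cent$degree)]
  out <- list(
    n_participants = object$n,
    n_groups = length(object$groups),
    n_edges = nrow(object$edges),
    weight_range = if (nrow(object$edges)) range(object$edges$weight) else c(NA, NA),
    isolated = cent$group[cent$degree == 0],
    hub = hub,
    hub_degree = max(cent$degree),
    modularity = object$modularity,
    module_sizes = if (!is.null(object$partition)) table(object$partition),
    centralities = cent)
  class(out) <- "summary.ccn"
  out
}

#' @export
print.summary.ccn <- function(x, ...) {
  cat("CCN summary\n")
  cat("  nodes:", x$n_groups, " edges:", x$n_edges,
      " participants:", x$n_participants, "\n")
  if (x$n_edges)
    cat("  edge weights:", paste(round(x$weight_range, 3), collapse = " to "), "\n")
  cat("  hub:", x$hub, "(degree", paste0(x$hub_degree, ")"), "\n")
  if (length(x$isolated))
    cat("  isolated nodes:", paste(x$isolated, collapse = ", "), "\n")
  if (!is.null(x$module_sizes))
    cat("  modules:", paste(x$module_sizes, collapse = "/"),
        "nodes; modularity", round(x$modularity, 3), "\n")
  invisible(x)
}

#' Plot a co-consumption network
#'
#' Node area scales with the consumption score, edge width with the mean
#' validated correlation, node color with the module.
#'
#' @param x a `ccn` fit.
#' @param ... passed to [igraph::plot.igraph()].
#' @export
plot.ccn <- function(x, ...) {
  g <- x$graph
  w <- igraph::V(g)$weight
  size <- 4 + 10 * sqrt(w / max(w, 1))
  cols <- rep("grey80", igraph::vcount(g))
  if (!is.null(x$partition)) {
    pal <- grDevices::hcl.colors(max(x$partition), "Dark 3")
    m <- x$partition[igraph::V(g)$name]
    cols[!is.na(m)] <- pal[m[!is.na(m)]]
  }
  ew <- if (igraph::ecount(g)) 1 + 4 * (igraph::E(g)$weight -
                                          min(igraph::E(g)$weight)) else 1
  igraph::plot.igraph(g, vertex.size = size, vertex.color = cols,
                      edge.width = ew, vertex.label.cex = 0.6, ...)
  invisible(x)
}

as_ccn_graph <- function(x) {
  if (inherits(x, "ccn")) x$graph
  else if (inherits(x, "igraph")) x
  else stop("expected a 'ccn' fit or an igraph graph")
}

#' Node centralities of a CCN
#'
#' Degree is the raw edge count. Betweenness is shortest-path betweenness on
#' the unweighted topology, normalized by (N-1)(N-2)/2 so it lies in \[0, 1\].
#' Closeness uses the Wasserman-Faust within-component form scaled by
#' (reachable - 1)/(N - 1); isolated nodes score 0 on all three.
#'
#' @param x a `ccn` fit or igraph graph.
#' @return data frame with columns group, weight (consumption score, if
#'   present), degree, betweenness, closeness, module (if partitioned).
#' @export
centralities <- function(x) {
  g <- as_ccn_graph(x)
  N <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  norm <- if (N > 2) (N - 1) * (N - 2) / 2 else 1
  btw <- btw / norm
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(N), function(i) {
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    r <- length(fin)
    if (r == 0 || N == 1) return(0)
    (r / (N - 1)) * (r / sum(fin))
  }, numeric(1))
  out <- data.frame(group = igraph::V(g)$name,
                    degree = as.integer(deg),
                    betweenness = unname(btw),
                    closeness = clo,
                    stringsAsFactors = FALSE)
  if (!is.null(igraph::V(g)$weight))
    out$weight <- igraph::V(g)$weight
  if (inherits(x, "ccn") && !is.null(x$partition)) {
    out$module <- unname(x$partition[out$group])
  }
  rownames(out) <- NULL
  out
}

#' Maximal cliques of a CCN
#'
#' @param x a `ccn` fit or igraph graph.
#' @param min_size smallest clique size to report.
#' @return list of character vectors (each sorted), ordered by decreasing
#'   size then lexicographically — a deterministic enumeration.
#' @export
ccn_cliques <- function(x, min_size = 2L) {
  g <- as_ccn_graph(x)
  cl <- igraph::max_cliques(g, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  keys <- vapply(cl, paste, character(1), collapse = "|")
  cl[order(-lengths(cl), keys)]
}

#' Module density as connections per node
#'
#' Number of edges with both endpoints inside the node set divided by the
#' set size — the "connection per node" density used to compare module
#' cohesion (not the conventional 2m/n(n-1) graph density).
#'
#' @param x a `ccn` fit or igraph graph.
#' @param nodes character vector of node names.
#' @return edges per node (a non-negative real).
#' @export
module_density <- function(x, nodes) {
  g <- as_ccn_graph(x)
  if (length(nodes) == 0) stop("empty node set")
  missing_nodes <- setdiff(nodes, igraph::V(g)$name)
  if (length(missing_nodes))
    stop("nodes not in graph: ", paste(missing_nodes, collapse = ", "))
  sub <- igraph::induced_subgraph(g, nodes)
  igraph::ecount(sub) / length(nodes)
}

#' Export a CCN to plain-text files
#'
#' Writes `edges.csv` (source, target, rho), `nodes.csv` (name, weight,
#' degree, betweenness, closeness, module) and `network.graphml`.
#'
#' @param fit a `ccn` fit.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix (default none).
#' @return the directory, invisibly.
#' @export
write_ccn <- function(fit, dir, prefix = "") {
  if (!inherits(fit, "ccn")) stop("expected a ccn fit")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- fit$edges
  names(edges) <- c("source", "target", "rho")
  utils::write.csv(edges, file.path(dir, paste0(prefix, "edges.csv")),
                   row.names = FALSE)
  utils::write.csv(centralities(fit),
                   file.path(dir, paste0(prefix, "nodes.csv")),
                   row.names = FALSE)
  igraph::write_graph(fit$graph,
                      file.path(dir, paste0(prefix, "network.graphml")),
                      format = "graphml")
  invisible(dir)
}
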