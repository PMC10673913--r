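# Stratified CCNs, group-differential networks and the age-trend network.

# Row-index sets per stratum; errors name strata that are empty/too small.
strata_indices <- function(covariates, by = c("sex", "disease", "age"),
                           control = ccn_control()) {
  by <- match.arg(by)
  idx <- switch(by,
    sex = list(male = which(covariates$sex == "male"),
               female = which(covariates$sex == "female")),
    disease = list(
      normal = which(covariates$cap < control$cap_cutoffs[1]),
      nafld = which(covariates$cap >= control$cap_cutoffs[3])),
    age = list(
      young = which(covariates$age < control$age_cutoffs[1]),
      middle = which(covariates$age >= control$age_cutoffs[1] &
                       covariates$age <= control$age_cutoffs[2]),
      old = which(covariates$age > control$age_cutoffs[2])))
  min_n <- ceiling(4 / min(control$split_fraction,
                           1 - control$split_fraction))
  small <- names(idx)[lengths(idx) < min_n]
  if (length(small))
    stop("stratum too small for split-half validation: ",
         paste(small, collapse = ", "))
  idx
}

#' Stratified co-consumption networks
#'
#' Runs the full CCN pipeline separately within each stratum of the cohort,
#' with identical control parameters. Strata: `sex` = male vs female;
#' `disease` = normal liver (CAP below the first cutoff, 238 dB/m) vs NAFLD
#' (CAP at or above the third cutoff, 293 dB/m), the intermediate range being
#' excluded; `age` = under 30, 30-50 inclusive, over 50 years.
#'
#' @param intake intake matrix.
#' @param covariates covariate table matching the intake participants.
#' @param by stratification rule: "sex", "disease" or "age".
#' @param control a [ccn_control()].
#' @param seed global seed; each stratum gets a derived seed.
#' @return named list of `ccn` fits, one per stratum.
#' @export
stratified_ccn <- function(intake, covariates, by = c("sex", "disease", "age"),
                           control = ccn_control(), seed = 1L) {
  by <- match.arg(by)
  intake <- validate_intake(intake)
  covariates <- validate_covariates(covariates, rownames(intake))
  idx <- strata_indices(covariates, by, control)
  fits <- lapply(names(idx), function(s) {
    ccn(intake[idx[[s]], , drop = FALSE], control = control,
        seed = derive_seed(seed, paste0("stratum_", by, "_", s)))
  })
  names(fits) <- names(idx)
  fits
}

edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
}

#' Differential co-consumption network
#'
#' The symmetric difference of two stratum CCN edge sets over the same node
#' universe: an edge enters iff it appears in exactly one stratum network,
#' weighted 1 and tagged with its stratum of origin. Node weight is the
#' degree within the differential network.
#'
#' @param graph_a,graph_b `ccn` fits or igraph graphs with identical node
#'   sets.
#' @param origins length-2 character vector naming the two strata.
#' @return object of class `ccn_diff`: list with `edges` (from, to, origin),
#'   `graph` (igraph with edge attribute `origin`), `origins`.
#' @export
differential_ccn <- function(graph_a, graph_b, origins = c("A", "B")) {
  ga <- as_ccn_graph(graph_a)
  gb <- as_ccn_graph(graph_b)
  if (!setequal(igraph::V(ga)$name, igraph::V(gb)$name))
    stop("node universes differ between the two networks")
  ka <- edge_keys(ga)
  kb <- edge_keys(gb)
  only_a <- setdiff(ka, kb)
  only_b <- setdiff(kb, ka)
  split_key <- function(k) do.call(rbind, strsplit(k, "|", fixed = TRUE))
  edges <- data.frame(from = character(0), to = character(0),
                      origin = character(0), stringsAsFactors = FALSE)
  if (length(only_a) + length(only_b) > 0) {
    mat <- rbind(if (length(only_a)) split_key(only_a),
                 if (length(only_b)) split_key(only_b))
    edges <- data.frame(from = mat[, 1], to = mat[, 2],
                        origin = rep(origins, c(length(only_a), length(only_b))),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(igraph::V(ga)$name),
                          stringsAsFactors = FALSE))
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  igraph::V(g)$weight <- igraph::degree(g)
  out <- list(edges = edges, graph = g, origins = origins)
  class(out) <- "ccn_diff"
  out
}

#' @export
print.ccn_diff <- function(x, ...) {
  tab <- table(factor(x$edges$origin, levels = x$origins))
  cat("Differential co-consumption network:", nrow(x$edges),
      "stratum-exclusive edges\n")
  cat(" ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Increasing-correlation rule for age-trend edges
#'
#' An edge is kept when its per-stratum correlations either increase
#' strictly across the three age strata (young < middle < old) or rise by
#' more than `delta` from the youngest to the oldest stratum.
#'
#' @param r_young,r_middle,r_old per-stratum Spearman correlations.
#' @param delta minimum oldest-minus-youngest increase for the second rule
#'   (default 0.25).
#' @param strict require strict monotonicity across all three strata for the
#'   first rule; `FALSE` weakens it to old > young.
#' @return logical vector.
#' @export
trend_rule <- function(r_young, r_middle, r_old, delta = 0.25, strict = TRUE) {
  rule1 <- if (strict) r_young < r_middle & r_middle < r_old
  else r_old > r_young
  rule2 <- (r_old - r_young) > delta
  out <- rule1 | rule2
  out[is.na(out)] <- FALSE
  out
}

#' Age-trend co-consumption network
#'
#' Splits the cohort into three age strata (< 30, 30-50, > 50 by default),
#' computes each pair's full-stratum Spearman correlation per stratum, and
#' keeps the pairs that are significantly positively correlated in the
#' oldest stratum (the eligibility rule, configurable) and satisfy
#' [trend_rule()]. Edges are tagged within/between module against a
#' reference partition; the trend magnitude is r(old) - r(young).
#'
#' @param intake intake matrix.
#' @param covariates covariate table.
#' @param partition optional named module-id vector used to tag edges.
#' @param control a [ccn_control()] (supplies `age_cutoffs` and `alpha`).
#' @param delta threshold of the second trend rule (default 0.25).
#' @param strict strict three-stratum monotonicity for the first rule.
#' @param eligibility stratum in which significance+positivity is required:
#'   "oldest" (default), "all" or "any".
#' @return object of class `ccn_trend`: list with `edges` (from, to,
#'   r_young, r_middle, r_old, magnitude, relation), `strata_n`, `graph`.
#' @export
age_trend <- function(intake, covariates, partition = NULL,
                      control = ccn_control(), delta = 0.25, strict = TRUE,
                      eligibility = c("oldest", "all", "any")) {
  eligibility <- match.arg(eligibility)
  intake <- validate_intake(intake)
  covariates <- validate_covariates(covariates, rownames(intake))
  idx <- strata_indices(covariates, "age", control)
  cors <- lapply(idx, function(i) spearman_pairwise(intake, i))
  G <- ncol(intake)
  ut <- upper.tri(matrix(0, G, G))
  sig <- lapply(cors, function(co)
    !is.na(co$p) & co$p < control$alpha & co$rho > 0)
  eligible <- switch(eligibility,
    oldest = sig$old,
    all = sig$young & sig$middle & sig$old,
    any = sig$young | sig$middle | sig$old)
  kept <- eligible & ut &
    trend_rule(cors$young$rho, cors$middle$rho, cors$old$rho,
               delta = delta, strict = strict)
  kept[is.na(kept)] <- FALSE
  ij <- which(kept, arr.ind = TRUE)
  edges <- data.frame(from = colnames(intake)[ij[, 1]],
                      to = colnames(intake)[ij[, 2]],
                      r_young = cors$young$rho[ij],
                      r_middle = cors$middle$rho[ij],
                      r_old = cors$old$rho[ij],
                      stringsAsFactors = FALSE)
  edges$magnitude <- edges$r_old - edges$r_young
  if (!is.null(partition)) {
    m1 <- partition[edges$from]
    m2 <- partition[edges$to]
    edges$relation <- ifelse(is.na(m1) | is.na(m2), "unassigned",
                             ifelse(m1 == m2, "within", "between"))
  } else {
    edges$relation <- NA_character_
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = colnames(intake), stringsAsFactors = FALSE))
  if (nrow(edges)) {
    igraph::E(g)$trend_magnitude <- edges$magnitude
    igraph::E(g)$module_relation <- edges$relation
  }
  igraph::V(g)$weight <- igraph::degree(g)
  out <- list(edges = edges, strata_n = lengths(idx), graph = g)
  class(out) <- "ccn_trend"
  out
}

#' @export
print.ccn_trend <- function(x, ...) {
  cat("Age-trend co-consumption network:", nrow(x$edges), "edges\n")
  cat("  strata sizes:",
      paste(names(x$strata_n), x$strata_n, sep = "=", collapse = ", "), "\n")
  if (nrow(x$edges) && !all(is.na(x$edges$relation))) {
    tab <- table(x$edges$relation)
    cat("  module relation:",
        paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export a differential or trend network
#'
#' Writes a GraphML file (edge attributes `origin` or `trend_magnitude` /
#' `module_relation`) and a CSV edge list.
#'
#' @param x a `ccn_diff` or `ccn_trend`.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return the directory, invisibly.
#' @export
write_diff <- function(x, dir, prefix = "diff_") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(x$edges, file.path(dir, paste0(prefix, "edges.csv")),
                   row.names = FALSE)
  g <- x$graph
  if (inherits(x, "ccn_diff") && nrow(x$edges))
    igraph::E(g)$origin <- x$edges$origin
  igraph::write_graph(g, file.path(dir, paste0(prefix, "network.graphml")),
                      format = "graphml")
  invisible(dir)
}
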