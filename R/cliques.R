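# Module-related cliques: consumer counts and chi-square/FDR association
# tests between the two module member groups.

#' Count participants consuming every food group of a clique
#'
#' A participant "consumes" a clique when their binarized indicator is 1 for
#' all of its food groups.
#'
#' @param clique character vector of food-group names (non-empty).
#' @param binarized 0/1 matrix from [binarize()].
#' @param ids participant IDs to count over (default: all rows).
#' @return integer count.
#' @export
clique_consumers <- function(clique, binarized, ids = rownames(binarized)) {
  if (length(clique) == 0) stop("empty clique")
  missing_groups <- setdiff(clique, colnames(binarized))
  if (length(missing_groups))
    stop("clique groups not in binarized matrix: ",
         paste(missing_groups, collapse = ", "))
  b <- binarized[ids, clique, drop = FALSE]
  sum(rowSums(b) == length(clique))
}

# 2x2 Pearson chi-square without continuity correction (configurable), with
# a flag when any expected cell count falls below 5.
chisq_2x2 <- function(tab, correct = FALSE) {
  if (all(tab[, 1] == 0) || all(tab[, 2] == 0) ||
      all(tab[1, ] == 0) || all(tab[2, ] == 0))
    return(list(p = 1, statistic = 0, low_expected = TRUE))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(p = unname(ht$p.value), statistic = unname(ht$statistic),
       low_expected = any(ht$expected < 5))
}

#' Test module-related cliques for differential consumption
#'
#' Takes the maximal cliques of the fitted network whose nodes all carry the
#' same module label, counts all-group consumers among unhealthy-module and
#' healthy-module members, and compares the two proportions by a Pearson
#' chi-square test (no continuity correction by default). P-values are
#' Benjamini-Hochberg adjusted across the tested cliques; a clique is
#' "related" to its module when the adjusted p-value is below `fdr_level`.
#'
#' @param fit a `ccn` fit (supplies graph, partition and binarized matrix),
#'   or a list of cliques (character vectors) if `binarized` and `partition`
#'   are given explicitly.
#' @param membership oriented membership data frame (labels "unhealthy" /
#'   "healthy" / "other"), e.g. from [orient_modules()].
#' @param module_names named map from module id to "unhealthy"/"healthy"
#'   (from [orient_modules()]); required when `fit` is a `ccn`.
#' @param binarized,partition required when `fit` is a plain clique list.
#' @param min_size smallest clique size tested (default 4).
#' @param fdr_level adjusted-p cutoff for the related flag.
#' @param correct Yates continuity correction (default FALSE).
#' @return data frame with one row per tested clique: size, members, module,
#'   counts and percentages per member group, p, p_adjusted, related,
#'   low_expected.
#' @export
test_cliques <- function(fit, membership, module_names = NULL,
                         binarized = NULL, partition = NULL,
                         min_size = 4L, fdr_level = 0.05, correct = FALSE) {
  if (inherits(fit, "ccn")) {
    cliques <- ccn_cliques(fit, min_size = min_size)
    binarized <- fit$binarized
    partition <- fit$partition
  } else {
    cliques <- fit
    if (is.null(binarized) || is.null(partition))
      stop("binarized and partition are required with an explicit clique list")
    cliques <- cliques[lengths(cliques) >= min_size]
  }
  if (is.null(partition)) stop("no module partition available")
  if (is.null(module_names)) {
    mods <- sort(unique(unname(partition)))
    module_names <- stats::setNames(as.character(mods), mods)
  }
  ids_u <- membership$id[membership$label == "unhealthy"]
  ids_h <- membership$id[membership$label == "healthy"]
  if (length(ids_u) == 0 || length(ids_h) == 0)
    stop("both member groups must be non-empty")
  # keep cliques whose nodes all share one module label
  home <- vapply(cliques, function(cl) {
    m <- unique(unname(partition[cl]))
    if (length(m) == 1 && !is.na(m)) as.character(m) else NA_character_
  }, character(1))
  keep <- !is.na(home)
  cliques <- cliques[keep]
  home <- home[keep]
  if (length(cliques) == 0)
    return(data.frame(size = integer(0), members = character(0),
                      module = character(0), n_unhealthy = integer(0),
                      pct_unhealthy = numeric(0), n_healthy = integer(0),
                      pct_healthy = numeric(0), p = numeric(0),
                      p_adjusted = numeric(0), related = logical(0),
                      low_expected = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(cliques), function(i) {
    cl <- cliques[[i]]
    cu <- clique_consumers(cl, binarized, ids_u)
    ch <- clique_consumers(cl, binarized, ids_h)
    tab <- rbind(c(cu, length(ids_u) - cu), c(ch, length(ids_h) - ch))
    ht <- chisq_2x2(tab, correct = correct)
    data.frame(size = length(cl), members = paste(cl, collapse = "/"),
               module = unname(module_names[home[i]]),
               n_unhealthy = cu, pct_unhealthy = 100 * cu / length(ids_u),
               n_healthy = ch, pct_healthy = 100 * ch / length(ids_h),
               p = ht$p, low_expected = ht$low_expected,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out$related <- out$p_adjusted < fdr_level
  out <- out[order(-out$size, out$members), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("size", "members", "module", "n_unhealthy", "pct_unhealthy",
          "n_healthy", "pct_healthy", "p", "p_adjusted", "related",
          "low_expected")]
}
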