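# End-to-end orchestration: fit the CCN, assign and compare members, build
# differential and age-trend networks, test cliques, and export everything.

#' Run the full co-consumption analysis
#'
#' Executes the whole pipeline on an intake matrix and covariate table:
#' binarization, split-half edge validation, graph assembly, consensus
#' label-propagation modules, hypergeometric participant membership (modules
#' oriented so the higher-member-CAP one is "unhealthy"), member covariate
#' comparison, sex- and disease-differential networks, the age-trend
#' network and module-related clique tests. All randomness derives from the
#' single `seed` through per-stage seeds.
#'
#' @param intake intake matrix (g/day).
#' @param covariates covariate table matching the intake participants.
#' @param control a [ccn_control()].
#' @param seed global seed.
#' @param out_dir optional directory: when given, all networks, tables, a
#'   JSON summary and a log (with the echoed configuration and resolved
#'   per-stage seeds) are written there.
#' @return object of class `ccn_analysis`: list with `fit`, `membership`,
#'   `module_names`, `comparison`, `diff_sex`, `diff_disease`, `trend`,
#'   `cliques`, `summary` (a flat list of headline numbers), `control`,
#'   `seed`.
#' @export
ccn_analysis <- function(intake, covariates, control = ccn_control(),
                         seed = 1L, out_dir = NULL) {
  intake <- validate_intake(intake)
  covariates <- validate_covariates(covariates, rownames(intake))
  stage <- "network construction"
  res <- tryCatch({
    fit <- ccn(intake, control = control, seed = seed)
    if (is.null(fit$partition))
      stop("network is edgeless; no downstream analysis possible")

    stage <- "module membership"
    membership <- hypergeometric_membership(fit$binarized, fit$partition,
                                            control$p_threshold)
    oriented <- orient_modules(membership, covariates)
    membership <- oriented$membership
    module_names <- oriented$module_names

    stage <- "member comparison"
    comparison <- compare_members(membership, covariates,
                                  cap_cutoffs = control$cap_cutoffs)

    stage <- "sex differential network"
    by_sex <- stratified_ccn(intake, covariates, "sex", control, seed)
    diff_sex <- differential_ccn(by_sex$male, by_sex$female,
                                 origins = c("male", "female"))

    stage <- "disease differential network"
    by_dis <- stratified_ccn(intake, covariates, "disease", control, seed)
    diff_disease <- differential_ccn(by_dis$normal, by_dis$nafld,
                                     origins = c("normal", "nafld"))

    stage <- "age trend network"
    trend <- age_trend(intake, covariates, fit$partition, control)

    stage <- "clique association"
    cliques <- test_cliques(fit, membership, module_names,
                            min_size = control$min_clique,
                            fdr_level = control$fdr_level)

    stage <- "summary"
    cent <- centralities(fit)
    mod_sizes <- lapply(names(module_names), function(m)
      sum(fit$partition == as.integer(m)))
    names(mod_sizes) <- unname(module_names)
    dens <- lapply(names(module_names), function(m)
      module_density(fit, names(fit$partition)[fit$partition == as.integer(m)]))
    names(dens) <- unname(module_names)
    mcounts <- table(factor(membership$label,
                            levels = c("unhealthy", "healthy", "other")))
    capm <- vapply(c("unhealthy", "healthy"), function(l)
      mean(covariates$cap[match(membership$id[membership$label == l],
                                covariates$id)]), numeric(1))
    summary_list <- list(
      n_participants = fit$n,
      n_groups = length(fit$groups),
      n_edges = nrow(fit$edges),
      n_isolated = sum(cent$degree == 0),
      hub = cent$group[which.max(cent$degree)],
      hub_degree = max(cent$degree),
      modularity = fit$modularity,
      n_modules = length(unique(fit$partition)),
      module_sizes = mod_sizes,
      module_density = dens,
      membership_counts = as.list(mcounts),
      mean_cap_members = as.list(capm),
      n_diff_sex_edges = nrow(diff_sex$edges),
      n_diff_disease_edges = nrow(diff_disease$edges),
      n_trend_edges = nrow(trend$edges),
      n_related_cliques = sum(cliques$related))

    list(fit = fit, membership = membership, module_names = module_names,
         comparison = comparison, diff_sex = diff_sex,
         diff_disease = diff_disease, trend = trend, cliques = cliques,
         summary = summary_list, control = control, seed = as.integer(seed))
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "ccn_analysis"
  if (!is.null(out_dir)) write_analysis(res, out_dir)
  res
}

#' @export
print.ccn_analysis <- function(x, ...) {
  s <- x$summary
  cat("Co-consumption analysis (seed", x$seed, ")\n")
  cat("  network:", s$n_groups, "nodes,", s$n_edges, "edges,",
      s$n_isolated, "isolated; hub:", s$hub,
      "(degree", paste0(s$hub_degree, ")"), "\n")
  cat("  modules:", paste(names(s$module_sizes), unlist(s$module_sizes),
                          sep = "=", collapse = ", "),
      "; modularity", round(s$modularity, 3), "\n")
  cat("  density (edges/node):",
      paste(names(s$module_density),
            round(unlist(s$module_density), 2), sep = "=", collapse = ", "), "\n")
  cat("  members:", paste(names(s$membership_counts),
                          unlist(s$membership_counts),
                          sep = "=", collapse = ", "), "\n")
  cat("  member mean CAP:",
      paste(names(s$mean_cap_members),
            round(unlist(s$mean_cap_members), 1), sep = "=", collapse = ", "),
      "dB/m\n")
  cat("  differential edges: sex", s$n_diff_sex_edges,
      ", disease", s$n_diff_disease_edges,
      "; trend edges:", s$n_trend_edges,
      "; related cliques:", s$n_related_cliques, "\n")
  invisible(x)
}

# Serialize every artifact of an analysis into a directory.
write_analysis <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ccn(res$fit, out_dir)
  utils::write.csv(res$membership, file.path(out_dir, "membership.csv"),
                   row.names = FALSE)
  utils::write.csv(res$comparison, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cliques, file.path(out_dir, "cliques.csv"),
                   row.names = FALSE)
  write_diff(res$diff_sex, out_dir, prefix = "diff_sex_")
  write_diff(res$diff_disease, out_dir, prefix = "diff_disease_")
  write_diff(res$trend, out_dir, prefix = "trend_")
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  ctl <- res$control
  log_lines <- c(
    paste0("ccnet analysis log ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("global seed: ", res$seed),
    paste0("derived seed [edges]: ", derive_seed(res$seed, "edges")),
    paste0("derived seed [communities]: ",
           derive_seed(res$seed, "communities")),
    "config:",
    paste0("  ", names(unclass(ctl)), " = ",
           vapply(unclass(ctl), function(v) paste(v, collapse = ","),
                  character(1))))
  writeLines(log_lines, file.path(out_dir, "analysis.log"))
  invisible(out_dir)
}
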