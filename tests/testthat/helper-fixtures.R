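# Shared fixture builders.

# Membership table + binarized matrix with exact all-clique consumer counts
# per member group; one disjoint column block per clique.
clique_fixture <- function(counts_u, counts_h, n_u = 323, n_h = 326,
                           clique_sizes = rep(4, length(counts_u))) {
  n_cliques <- length(counts_u)
  ids <- c(sprintf("U%03d", seq_len(n_u)), sprintf("H%03d", seq_len(n_h)))
  membership <- data.frame(
    id = ids, label = rep(c("unhealthy", "healthy"), c(n_u, n_h)),
    stringsAsFactors = FALSE)
  groups <- unlist(lapply(seq_len(n_cliques), function(j)
    paste0("c", j, "_", seq_len(clique_sizes[j]))))
  b <- matrix(0L, n_u + n_h, length(groups),
              dimnames = list(ids, groups))
  for (j in seq_len(n_cliques)) {
    cols <- grep(paste0("^c", j, "_"), groups, value = TRUE)
    b[seq_len(counts_u[j]), cols] <- 1L
    b[n_u + seq_len(counts_h[j]), cols] <- 1L
  }
  cliques <- lapply(seq_len(n_cliques), function(j)
    grep(paste0("^c", j, "_"), groups, value = TRUE))
  list(membership = membership, binarized = b, cliques = cliques,
       partition = stats::setNames(rep(1L, length(groups)), groups))
}
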