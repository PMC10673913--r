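# Internal helpers: seed management and partition comparison.

# Deterministically derive a per-stage seed from a global seed and a stage name.
# Kept below 2^31 so it is a valid R integer seed; arithmetic stays exact in
# doubles (products < 2^53).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp))
  as.integer(((abs(seed) %% 100003) * 10007 + h) %% 2147483647)
}

# Set the RNG seed and return a function that restores the caller's RNG state.
# Usage: restore <- local_seed(seed); on.exit(restore(), add = TRUE)
local_seed <- function(seed) {
  env <- globalenv()
  restore <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    function() assign(".Random.seed", old, envir = env)
  } else {
    function() {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    }
  }
  set.seed(seed)
  restore
}

# Structural checks for a numeric variable matrix (used by the correlation
# machinery, which is rank-based and therefore sign-agnostic; full intake
# semantics, including non-negativity, are enforced by validate_intake).
check_numeric_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a numeric matrix")
  if (is.null(colnames(x))) stop("matrix must have column names")
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  if (anyNA(x)) stop("matrix contains missing values")
  x
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects,
#' used here to score recovered network modules against planted blocks.
#' 1 means identical groupings (up to label names), 0 is the expectation
#' under independent random labelings.
#'
#' @param a,b vectors of equal length giving the two labelings; names are
#'   ignored, positions are matched.
#' @return a number in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2) return(1)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (nij - expected) / denom
}
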