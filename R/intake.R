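# Intake matrices: validation, file I/O, item aggregation, quartile
# binarization and consumption scores.

#' Validate a participant-by-food-group intake matrix
#'
#' An intake matrix is a plain numeric matrix: one row per participant
#' (rownames are participant IDs), one column per food group (colnames),
#' values in grams per day. Validation rejects missing values (no silent
#' imputation), negative intakes, and duplicated participant or group names,
#' naming the offending cells.
#'
#' @param x numeric matrix or a data frame coercible to one (a non-numeric
#'   first column, if present, is taken as participant IDs).
#' @return the validated numeric matrix (invisibly the same data).
#' @export
validate_intake <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) >= 2 && !is.numeric(x[[1]])) {
      ids <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("intake must be a numeric matrix of g/day values")
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  if (is.null(colnames(x))) stop("intake matrix must have food-group column names")
  dup_id <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_id))
    stop("duplicated participant IDs: ", paste(dup_id, collapse = ", "))
  dup_g <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_g))
    stop("duplicated food-group names: ", paste(dup_g, collapse = ", "))
  bad_cells <- function(idx, what) {
    idx <- idx[seq_len(min(nrow(idx), 5L)), , drop = FALSE]
    cells <- paste0("participant '", rownames(x)[idx[, 1]], "', group '",
                    colnames(x)[idx[, 2]], "'", collapse = "; ")
    stop(what, " intake value at: ", cells, call. = FALSE)
  }
  if (anyNA(x)) bad_cells(which(is.na(x), arr.ind = TRUE), "missing")
  if (any(x < 0)) bad_cells(which(x < 0, arr.ind = TRUE), "negative")
  storage.mode(x) <- "double"
  x
}

#' Read an intake matrix from a delimited file
#'
#' Expects a header row of food-group names and one row per participant whose
#' first field is the participant ID. The separator defaults to tab for
#' `.tsv`/`.txt` files and comma otherwise.
#'
#' @param path file path.
#' @param sep field separator; `NULL` to infer from the extension.
#' @return validated intake matrix.
#' @seealso [write_intake()], [validate_intake()]
#' @export
read_intake <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an ID column plus at least one food group")
  ids <- as.character(df[[1]])
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- colnames(x)[!vapply(df[-1], is.numeric, logical(1))]
    stop("non-numeric intake columns: ", paste(bad, collapse = ", "))
  }
  rownames(x) <- ids
  validate_intake(x)
}

#' Write an intake matrix to CSV
#'
#' @param x intake matrix.
#' @param path output path; the first column is named `id`.
#' @export
write_intake <- function(x, path) {
  x <- validate_intake(x)
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a food item-to-group mapping
#'
#' Accepts a two-column delimited file (`item,group`) or, for `.yml`/`.yaml`
#' files, a YAML map of `group: [items...]` (requires the yaml package).
#'
#' @param path file path.
#' @return named character vector mapping item name to group name.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML mappings requires the 'yaml' package")
    lst <- yaml::read_yaml(path)
    map <- unlist(lapply(names(lst), function(g) {
      stats::setNames(rep(g, length(lst[[g]])), as.character(lst[[g]]))
    }))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("mapping file needs columns item, group")
    map <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  }
  dup <- unique(names(map)[duplicated(names(map))])
  if (length(dup)) stop("items mapped more than once: ", paste(dup, collapse = ", "))
  map
}

#' Aggregate food items into food groups
#'
#' Sums item columns belonging to the same group, per participant, so each
#' participant's total grams are conserved.
#'
#' @param x intake matrix whose columns are food items.
#' @param mapping named character vector (names = items, values = groups) as
#'   returned by [read_mapping()], or a two-column data frame (item, group).
#' @return intake matrix with one column per distinct group, in order of first
#'   appearance in the mapping.
#' @export
aggregate_items <- function(x, mapping) {
  x <- validate_intake(x)
  if (is.data.frame(mapping))
    mapping <- stats::setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
  unmapped <- setdiff(colnames(x), names(mapping))
  if (length(unmapped))
    stop("unmapped food items: ", paste(unmapped, collapse = ", "))
  map <- mapping[colnames(x)]
  groups <- unique(unname(map))
  out <- vapply(groups, function(g) {
    rowSums(x[, names(map)[map == g], drop = FALSE])
  }, numeric(nrow(x)))
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), groups))
  out
}

#' Binarize intake by the quartile consumer rule
#'
#' A participant is a "consumer" of a food group (indicator 1) when their
#' intake is strictly greater than the group's lower quartile computed over
#' all participants; otherwise 0 ("not consumed"). For zero-inflated groups
#' whose lower quartile is 0, consumers are exactly the participants with
#' non-zero intake. The rule is rank-based, so any strictly increasing
#' transformation of a column leaves the indicators unchanged.
#'
#' @param x intake matrix.
#' @param prob quantile level of the cut (default 0.25, the first quartile).
#' @param type quantile estimation type passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return integer 0/1 matrix with the same dimnames as `x`.
#' @export
binarize <- function(x, prob = 0.25, type = 7) {
  x <- validate_intake(x)
  q <- apply(x, 2, stats::quantile, probs = prob, type = type, names = FALSE)
  b <- sweep(x, 2, q, ">")
  storage.mode(b) <- "integer"
  b
}

#' Consumption score of each food group
#'
#' Number of participants labeled consumers after binarization; used as the
#' node weight (size) in the co-consumption network.
#'
#' @param b binarized matrix from [binarize()].
#' @return named integer vector, one entry per food group.
#' @export
consumption_score <- function(b) {
  if (!is.matrix(b) || !all(b %in% c(0L, 1L)))
    stop("expected a 0/1 binarized matrix")
  s <- colSums(b)
  storage.mode(s) <- "integer"
  s
}

#' Read a participant covariate table
#'
#' Requires columns `id`, `age` (years), `sex` (male/female), `bmi` (kg/m2),
#' `energy` (kcal/day) and `cap` (controlled attenuation parameter, dB/m).
#'
#' @param path CSV file path.
#' @return validated data frame with `sex` as a factor (levels male, female).
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_covariates(df)
}

#' Validate a covariate table
#'
#' @param df data frame with columns id, age, sex, bmi, energy, cap.
#' @param participants optional character vector of participant IDs the table
#'   must match exactly (e.g. the intake matrix rownames).
#' @return the validated data frame.
#' @export
validate_covariates <- function(df, participants = NULL) {
  need <- c("id", "age", "sex", "bmi", "energy", "cap")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariates missing columns: ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicated participant IDs in covariates")
  sex <- tolower(as.character(df$sex))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  df$sex <- factor(sex, levels = c("male", "female"))
  for (v in c("age", "bmi", "energy", "cap")) {
    if (anyNA(df[[v]])) stop("missing values in covariate: ", v)
    if (any(df[[v]] <= 0)) stop("non-positive values in covariate: ", v)
  }
  if (!is.null(participants)) {
    if (!setequal(df$id, participants))
      stop("covariate IDs do not match intake participants")
    df <- df[match(participants, df$id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}
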