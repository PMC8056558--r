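#' Construct a binary drug-target interaction matrix
#'
#' The interaction matrix Y is an n x m binary adjacency between drugs (rows)
#' and protein targets (columns); \code{Y[d, t] == 1} records a known
#' interaction. Identifiers are opaque strings (no KEGG-ID validation: the
#' method never inspects them).
#'
#' @param values n x m matrix of 0/1 values.
#' @param drug_ids length-n character vector, no duplicates.
#' @param target_ids length-m character vector, no duplicates.
#' @return an object of class \code{interaction_matrix} with fields
#'   \code{values}, \code{drug_ids}, \code{target_ids}.
#' @export
interaction_matrix <- function(values, drug_ids = rownames(values),
                               target_ids = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("interaction matrix needs at least one drug and one target")
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(nrow(values)))
  if (is.null(target_ids)) target_ids <- paste0("t", seq_len(ncol(values)))
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  if (length(drug_ids) != nrow(values) || length(target_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  check_no_duplicates(drug_ids, "drug identifiers")
  check_no_duplicates(target_ids, "target identifiers")
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("interaction matrix contains missing values")
  check_binary(values, "interaction matrix")
  dimnames(values) <- list(drug_ids, target_ids)
  structure(list(values = values, drug_ids = drug_ids,
                 target_ids = target_ids),
            class = "interaction_matrix")
}

#' Construct a binary fingerprint-drug matrix
#'
#' Z is an f x n binary matrix; bit k of drug d is 1 when substructure k is
#' present in the drug. Fingerprint length f is a property of the data (800
#' for the PaDEL fingerprints used on the public benchmarks), never
#' hard-coded.
#'
#' @param values f x n matrix of 0/1 values (bits x drugs).
#' @param bit_ids length-f character vector.
#' @param drug_ids length-n character vector; must later match the
#'   interaction matrix it is combined with (checked at combination time).
#' @return an object of class \code{fingerprint_matrix}.
#' @export
fingerprint_matrix <- function(values, bit_ids = rownames(values),
                               drug_ids = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("fingerprint matrix needs at least one bit and one drug")
  if (is.null(bit_ids)) bit_ids <- paste0("bit", seq_len(nrow(values)))
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(ncol(values)))
  bit_ids <- as.character(bit_ids)
  drug_ids <- as.character(drug_ids)
  if (length(bit_ids) != nrow(values) || length(drug_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  check_no_duplicates(bit_ids, "fingerprint bit identifiers")
  check_no_duplicates(drug_ids, "drug identifiers")
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("fingerprint matrix contains missing values")
  check_binary(values, "fingerprint matrix")
  dimnames(values) <- list(bit_ids, drug_ids)
  structure(list(values = values, bit_ids = bit_ids, drug_ids = drug_ids),
            class = "fingerprint_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  s <- dataset_statistics(x)
  cat(sprintf("interaction_matrix: %d drugs x %d targets, %d interactions (sparsity %.4f)\n",
              s$n_drugs, s$n_targets, s$n_interactions, s$sparsity))
  invisible(x)
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_matrix: %d bits x %d drugs, density %.3f\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

# shared reader for the tab-delimited dialect: identifiers in the header row
# and in the first column, 0/1 cells everywhere else
read_binary_tsv <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("%s: expected identifiers plus at least one data column", path))
  row_ids <- df[[1L]]
  cells <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- cells[is.na(num)][1]
    stop(sprintf("%s: non-numeric cell value '%s'", path, bad), call. = FALSE)
  }
  dimnames(num) <- list(row_ids, colnames(df)[-1L])
  num
}

#' Read a drug-target interaction matrix from a tab-delimited file
#'
#' Reads the tab-delimited adjacency dialect used by the public gold-standard
#' benchmark distributions: identifiers in the header row and first column,
#' 0/1 everywhere else. Some mirrors distribute the files with targets as
#' rows, so the orientation is an explicit argument rather than a guess --
#' silent transposition is the classic failure mode with these files.
#'
#' @param path file path.
#' @param orientation \code{"drugs_as_rows"} (default) or
#'   \code{"targets_as_rows"}; with the latter the matrix is transposed after
#'   reading so the returned object always has drugs as rows.
#' @param sep field separator, tab by default.
#' @return an \code{\link{interaction_matrix}}.
#' @export
read_interaction_matrix <- function(path,
                                    orientation = c("drugs_as_rows",
                                                    "targets_as_rows"),
                                    sep = "\t") {
  orientation <- match.arg(orientation)
  num <- read_binary_tsv(path, sep = sep)
  if (orientation == "targets_as_rows") num <- t(num)
  check_binary(num, sprintf("%s: interaction matrix", path))
  interaction_matrix(num)
}

#' Read a fingerprint-drug matrix from a delimited file
#'
#' Bits as rows, drugs as columns, identifiers in header/first column.
#'
#' @param path file path.
#' @param sep field separator, tab by default (use "," for CSV).
#' @return a \code{\link{fingerprint_matrix}}.
#' @export
read_fingerprint_matrix <- function(path, sep = "\t") {
  num <- read_binary_tsv(path, sep = sep)
  check_binary(num, sprintf("%s: fingerprint matrix", path))
  fingerprint_matrix(num)
}

#' Summary statistics for an interaction matrix
#'
#' Sparsity here follows the benchmark convention: the ratio between the
#' number of known interactions and the number of all possible drug-target
#' pairs, reported unrounded (display rounding is the caller's concern).
#'
#' @param Y an \code{\link{interaction_matrix}}.
#' @return a list with \code{n_drugs}, \code{n_targets},
#'   \code{n_interactions}, \code{sparsity}.
#' @export
dataset_statistics <- function(Y) {
  stopifnot(inherits(Y, "interaction_matrix"))
  n <- nrow(Y$values); m <- ncol(Y$values)
  k <- sum(Y$values)
  list(n_drugs = n, n_targets = m, n_interactions = as.integer(k),
       sparsity = k / (n * m))
}

#' Write a real-valued score matrix to a tab-delimited file
#'
#' @param scores n x m numeric matrix (finite values only).
#' @param drug_ids,target_ids identifier vectors matching the dimensions.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_score_matrix <- function(scores, drug_ids, target_ids, path) {
  scores <- as.matrix(scores)
  if (length(drug_ids) != nrow(scores) || length(target_ids) != ncol(scores))
    stop("score matrix dimensions do not match identifier lists")
  if (any(!is.finite(scores)))
    stop("score matrix contains non-finite values")
  df <- data.frame(id = as.character(drug_ids),
                   format(scores, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", as.character(target_ids))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a score matrix written by \code{write_score_matrix}
#'
#' @param path file path.
#' @return a list with \code{values}, \code{drug_ids}, \code{target_ids}.
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df[[1L]]
  list(values = vals, drug_ids = as.character(df[[1L]]),
       target_ids = colnames(df)[-1L])
}

#' Write an interaction, fingerprint or fingerprint-target matrix
#'
#' Emits the same tab-delimited dialect the readers consume (identifiers in
#' the header row and first column).
#'
#' @param x an \code{interaction_matrix}, \code{fingerprint_matrix} or
#'   binary-stage \code{fingerprint_target_matrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_binary_matrix <- function(x, path) {
  stopifnot(inherits(x, c("interaction_matrix", "fingerprint_matrix",
                          "fingerprint_target_matrix")))
  v <- x$values
  df <- data.frame(id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
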