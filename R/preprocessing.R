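#' Fingerprint-target matrices
#'
#' The densification step turns the sparse drug-target adjacency Y into a
#' fingerprint-target matrix W = Z Y that links chemical substructures to
#' targets via the drugs that contain them. W passes through three stages:
#' \code{raw} (nonnegative integer counts), \code{normalized} (min-max scaled
#' to [0,1]) and \code{binary} (any positive entry set to 1).
#'
#' @param values f x m matrix.
#' @param bit_ids,target_ids identifier vectors.
#' @param stage one of \code{"raw"}, \code{"normalized"}, \code{"binary"}.
#' @return an object of class \code{fingerprint_target_matrix}.
#' @export
fingerprint_target_matrix <- function(values, bit_ids = rownames(values),
                                      target_ids = colnames(values),
                                      stage = c("raw", "normalized", "binary")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("fingerprint-target matrix contains missing values")
  if (stage == "raw" && any(values < 0 | values != round(values)))
    stop("raw-stage entries must be nonnegative integer counts")
  if (stage == "normalized" && any(values < 0 | values > 1))
    stop("normalized-stage entries must lie in [0,1]")
  if (stage == "binary") check_binary(values, "binary-stage matrix")
  if (is.null(bit_ids)) bit_ids <- paste0("bit", seq_len(nrow(values)))
  if (is.null(target_ids)) target_ids <- paste0("t", seq_len(ncol(values)))
  dimnames(values) <- list(bit_ids, target_ids)
  structure(list(values = values, bit_ids = as.character(bit_ids),
                 target_ids = as.character(target_ids), stage = stage),
            class = "fingerprint_target_matrix")
}

#' @export
print.fingerprint_target_matrix <- function(x, ...) {
  cat(sprintf("fingerprint_target_matrix [%s]: %d bits x %d targets, density %.3f\n",
              x$stage, nrow(x$values), ncol(x$values), mean(x$values > 0)))
  invisible(x)
}

#' Multiply the fingerprint matrix by the interaction matrix
#'
#' W = Z Y: entry (k, t) counts the drugs d that both carry fingerprint bit k
#' and interact with target t. The drug axes of Z and Y must agree in both
#' content and order; a mismatch is an error, never a silent reindex.
#'
#' @param Z a \code{\link{fingerprint_matrix}} (f x n).
#' @param Y an \code{\link{interaction_matrix}} (n x m).
#' @return a raw-stage \code{\link{fingerprint_target_matrix}} (f x m).
#' @export
fingerprint_target_product <- function(Z, Y) {
  stopifnot(inherits(Z, "fingerprint_matrix"),
            inherits(Y, "interaction_matrix"))
  if (length(Z$drug_ids) != length(Y$drug_ids) ||
      !all(Z$drug_ids == Y$drug_ids))
    stop("drug axes of Z and Y do not match (count or order)")
  W <- Z$values %*% Y$values
  fingerprint_target_matrix(W, bit_ids = Z$bit_ids,
                            target_ids = Y$target_ids, stage = "raw")
}

#' Min-max normalize a raw fingerprint-target matrix
#'
#' A single global minimum and maximum over the whole matrix is used (not
#' per-column): downstream binarization maps any positive entry to 1 either
#' way, so the scope choice is immaterial for the pipeline, and global is the
#' simplest reproducible convention for the normalized intermediate. A
#' constant matrix maps to all zeros rather than dividing 0/0.
#'
#' @param W a raw-stage \code{\link{fingerprint_target_matrix}}.
#' @return the normalized-stage matrix. The raw global minimum is kept in
#'   the \code{raw_min} field so that \code{\link{binarize}} can honor the
#'   "raw count > 0" rule even when every raw entry is positive (min-max
#'   then maps the smallest positive count to 0).
#' @export
minmax_normalize <- function(W) {
  stopifnot(inherits(W, "fingerprint_target_matrix"))
  if (W$stage != "raw") stop("minmax_normalize expects a raw-stage matrix")
  lo <- min(W$values); hi <- max(W$values)
  vals <- if (hi > lo) (W$values - lo) / (hi - lo) else W$values * 0
  out <- fingerprint_target_matrix(vals, W$bit_ids, W$target_ids,
                                   "normalized")
  out$raw_min <- lo
  out
}

#' Binarize a normalized fingerprint-target matrix
#'
#' Any entry whose raw count was strictly positive represents at least one
#' drug linking the bit to the target, and becomes 1; true zeros stay 0. On
#' a normalized matrix this is the "> 0" rule, except in the degenerate case
#' where the raw global minimum itself was positive (recorded by
#' \code{\link{minmax_normalize}} as \code{raw_min}): there every cell was
#' linked, so all entries become 1.
#'
#' @param W a normalized-stage \code{\link{fingerprint_target_matrix}}.
#' @return the binary-stage matrix.
#' @export
binarize <- function(W) {
  stopifnot(inherits(W, "fingerprint_target_matrix"))
  if (W$stage != "normalized") stop("binarize expects a normalized-stage matrix")
  raw_min <- if (is.null(W$raw_min)) 0 else W$raw_min
  vals <- if (raw_min > 0) (W$values * 0) + 1 else (W$values > 0) * 1
  fingerprint_target_matrix(vals, W$bit_ids, W$target_ids, "binary")
}

#' Full pre-processing: product, min-max normalization, binarization
#'
#' Converts (Z, Y) into the binary fingerprint-target matrix the autoencoder
#' trains on. Equivalent to the existential rule
#' W(k, t) = 1 iff some drug d has Z[k, d] = 1 and Y[d, t] = 1.
#'
#' @param Z a \code{\link{fingerprint_matrix}}.
#' @param Y an \code{\link{interaction_matrix}}.
#' @return a binary-stage \code{\link{fingerprint_target_matrix}}.
#' @export
preprocess <- function(Z, Y) {
  binarize(minmax_normalize(fingerprint_target_product(Z, Y)))
}
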