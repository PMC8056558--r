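#' Project reconstructed fingerprint profiles back to drug-target scores
#'
#' Y_hat = t(Z) W_hat: the score for pair (d, t) is the dot product of drug
#' d's fingerprint bits with target t's reconstructed substructure profile.
#' Scores are unnormalized dot products, not probabilities (AUC/AUPR are
#' rank-based, so this is immaterial for evaluation); set
#' \code{normalize = TRUE} to divide each drug's row by its bit count, a
#' convenience beyond the published method.
#'
#' @param Z a \code{\link{fingerprint_matrix}} (f x n).
#' @param W_hat f x m numeric matrix of reconstructions.
#' @param normalize divide each row by the drug's number of set bits.
#' @return an object of class \code{score_matrix}: list with \code{values}
#'   (n x m), \code{drug_ids}, \code{target_ids}.
#' @export
predict_interactions <- function(Z, W_hat, normalize = FALSE) {
  stopifnot(inherits(Z, "fingerprint_matrix"))
  W_hat <- as.matrix(W_hat)
  if (nrow(Z$values) != nrow(W_hat))
    stop("fingerprint length of Z does not match the rows of W_hat")
  scores <- crossprod(Z$values, W_hat)
  if (normalize) {
    bits <- pmax(colSums(Z$values), 1)
    scores <- scores / bits
  }
  target_ids <- colnames(W_hat)
  if (is.null(target_ids)) target_ids <- paste0("t", seq_len(ncol(W_hat)))
  dimnames(scores) <- list(Z$drug_ids, target_ids)
  structure(list(values = scores, drug_ids = Z$drug_ids,
                 target_ids = target_ids),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d drugs x %d targets, range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Rank unknown drug-target pairs by predicted score
#'
#' Restricts to pairs with Y[d, t] == 0, sorts by score descending and
#' returns the top k. Ties are broken by (drug_id, target_id) lexicographic
#' order so the ranking is deterministic.
#'
#' @param scores a \code{score_matrix}.
#' @param Y the \code{\link{interaction_matrix}} of known interactions.
#' @param top_k number of pairs to return; if it exceeds the number of
#'   unknown pairs, all unknown pairs are returned.
#' @return data.frame with columns drug_id, target_id, score, rank.
#' @export
rank_novel <- function(scores, Y, top_k = 10L) {
  stopifnot(inherits(scores, "score_matrix"), inherits(Y, "interaction_matrix"))
  if (!identical(scores$drug_ids, Y$drug_ids) ||
      !identical(scores$target_ids, Y$target_ids))
    stop("scores and Y must share identifiers in the same order")
  unk <- which(Y$values == 0, arr.ind = TRUE)
  if (nrow(unk) == 0L)
    return(data.frame(drug_id = character(0), target_id = character(0),
                      score = numeric(0), rank = integer(0)))
  df <- data.frame(drug_id = scores$drug_ids[unk[, 1L]],
                   target_id = scores$target_ids[unk[, 2L]],
                   score = scores$values[unk],
                   stringsAsFactors = FALSE)
  ord <- order(-df$score, df$drug_id, df$target_id)
  df <- df[ord, , drop = FALSE]
  k <- min(as.integer(top_k), nrow(df))
  df <- df[seq_len(k), , drop = FALSE]
  df$rank <- seq_len(k)
  rownames(df) <- NULL
  df
}

#' Run the full pipeline: preprocess, train, reconstruct, predict
#'
#' Densifies (Z, Y) into the binary fingerprint-target matrix, trains the
#' denoising autoencoder on its target columns, reconstructs it and projects
#' back through the fingerprints to an n x m score matrix. With a fixed
#' config seed the result is bit-reproducible.
#'
#' @param Z a \code{\link{fingerprint_matrix}}.
#' @param Y an \code{\link{interaction_matrix}} with the same drug order.
#' @param config a \code{\link{training_config}}.
#' @param keep_intermediates attach W, W_hat and the trained parameters as
#'   attributes of the result.
#' @return a \code{score_matrix}.
#' @export
run_pipeline <- function(Z, Y, config = training_config(),
                         keep_intermediates = FALSE) {
  if (sum(Y$values) == 0)
    stop("no observed interactions: Y is all zeros, nothing to train on")
  W <- preprocess(Z, Y)
  params <- train_autoencoder(W, config)
  W_hat <- reconstruct(W, params)
  scores <- predict_interactions(Z, W_hat)
  if (keep_intermediates) {
    attr(scores, "W") <- W
    attr(scores, "W_hat") <- W_hat
    attr(scores, "params") <- params
  }
  scores
}
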