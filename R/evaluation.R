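#' Build a cross-validation plan
#'
#' Three scenarios probe increasingly hard generalization: \code{pairwise}
#' leaves out random drug-target pairs, \code{drugwise} leaves out whole drug
#' interaction profiles (new-drug cold start) and \code{targetwise} whole
#' target profiles (new-target cold start). Each repeat partitions the units
#' into \code{n_folds} folds whose sizes differ by at most one, using the
#' seeded generator.
#'
#' By default the pairwise scenario partitions the full n x m pair universe,
#' so each test fold carries its own negatives. \code{positives_only = TRUE}
#' instead folds only the known interactions; every zero pair then serves as
#' a test negative in every fold (the published description is ambiguous
#' between the two readings, so both are provided).
#'
#' @param Y an \code{\link{interaction_matrix}}.
#' @param scenario one of \code{"pairwise"}, \code{"drugwise"},
#'   \code{"targetwise"}.
#' @param n_folds number of folds (default 10).
#' @param n_repeats number of CV repetitions (default 5).
#' @param seed integer seed for the fold shuffles.
#' @param positives_only pairwise only: fold just the positive pairs.
#' @return a list of class \code{cv_plan} with the scenario, the unit table
#'   and a units x repeats fold-assignment matrix.
#' @export
make_cv_plan <- function(Y, scenario = c("pairwise", "drugwise", "targetwise"),
                         n_folds = 10L, n_repeats = 5L, seed = 1L,
                         positives_only = FALSE) {
  stopifnot(inherits(Y, "interaction_matrix"))
  scenario <- match.arg(scenario)
  n <- nrow(Y$values); m <- ncol(Y$values)
  n_folds <- as.integer(n_folds); n_repeats <- as.integer(n_repeats)
  units <- switch(scenario,
    pairwise = {
      if (positives_only) {
        idx <- which(Y$values == 1, arr.ind = TRUE)
        data.frame(drug = idx[, 1L], target = idx[, 2L])
      } else {
        expand.grid(drug = seq_len(n), target = seq_len(m))
      }
    },
    drugwise = data.frame(drug = seq_len(n)),
    targetwise = data.frame(target = seq_len(m)))
  n_units <- nrow(units)
  if (n_units < n_folds)
    stop(sprintf("only %d %s units available for %d folds",
                 n_units, scenario, n_folds))
  set.seed(seed)
  fold_assignment <- vapply(seq_len(n_repeats), function(r) {
    sample(rep(seq_len(n_folds), length.out = n_units))
  }, integer(n_units))
  structure(list(scenario = scenario, n_folds = n_folds,
                 n_repeats = n_repeats, seed = as.integer(seed),
                 positives_only = isTRUE(positives_only), units = units,
                 fold_assignment = fold_assignment,
                 n_drugs = n, n_targets = m),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %s, %d folds x %d repeats over %d units (seed %d)\n",
              x$scenario, x$n_folds, x$n_repeats, nrow(x$units), x$seed))
  invisible(x)
}

# linear indices (into Y$values) of the held-out cells for one fold
held_out_cells <- function(plan, fold, repeat_idx) {
  sel <- plan$fold_assignment[, repeat_idx] == fold
  u <- plan$units[sel, , drop = FALSE]
  n <- plan$n_drugs
  switch(plan$scenario,
    pairwise = (u$target - 1L) * n + u$drug,
    drugwise = as.vector(outer(u$drug, (seq_len(plan$n_targets) - 1L) * n, `+`)),
    targetwise = as.vector(outer(seq_len(n), (u$target - 1L) * n, `+`)))
}

#' Mask the held-out fold out of the training matrix
#'
#' Returns a copy of Y in which every held-out cell is set to zero: for
#' pairwise CV the held-out pairs, for drugwise/targetwise CV the entire
#' held-out rows/columns. No interaction information from the test fold
#' remains in the training matrix.
#'
#' @param Y an \code{\link{interaction_matrix}}.
#' @param plan a \code{\link{make_cv_plan}} result.
#' @param fold fold index in 1..n_folds.
#' @param repeat_idx repeat index in 1..n_repeats.
#' @return an \code{\link{interaction_matrix}}.
#' @export
mask_training_matrix <- function(Y, plan, fold, repeat_idx = 1L) {
  stopifnot(inherits(Y, "interaction_matrix"), inherits(plan, "cv_plan"))
  if (fold < 1L || fold > plan$n_folds) stop("fold index out of range")
  if (repeat_idx < 1L || repeat_idx > plan$n_repeats)
    stop("repeat index out of range")
  vals <- Y$values
  vals[held_out_cells(plan, fold, repeat_idx)] <- 0
  interaction_matrix(vals, Y$drug_ids, Y$target_ids)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' outranks a uniformly chosen negative, with ties counting one half.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in [0,1].
#' @export
auc_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  check_binary(labels, "labels")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("AUC is undefined when only one class is present")
  r <- rank(scores)                      # midranks handle ties as 1/2
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall curve
#'
#' Non-interpolated step summation sum_i (R_i - R_{i-1}) P_i over descending
#' score thresholds, with tied scores grouped at one threshold. With a
#' constant predictor this reduces to the positive prevalence; interpolated
#' average precision would inflate small-dataset scores.
#'
#' @param labels binary 0/1 vector with at least one positive.
#' @param scores numeric vector of the same length.
#' @return AUPR in [0,1].
#' @export
aupr_score <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  check_binary(labels, "labels")
  P <- sum(labels == 1)
  if (P == 0) stop("AUPR is undefined with zero positives")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # last index of each tied block = one threshold
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  n_pred <- seq_along(y)[last]
  prec <- tp / n_pred
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Run repeated cross-validation of the full pipeline
#'
#' For every repeat and fold: mask the held-out cells out of Y, rerun the
#' whole pipeline on the masked matrix (the fingerprint-target densification
#' is recomputed from the masked Y, so no held-out interaction leaks through
#' the pre-processing product), and score the held-out cells only. Per-fold
#' seeds derive deterministically from the config seed, the repeat and the
#' fold. Folds whose test labels are single-class are recorded as NA and
#' excluded from the means with a warning.
#'
#' @param Z a \code{\link{fingerprint_matrix}}.
#' @param Y an \code{\link{interaction_matrix}}.
#' @param config a \code{\link{training_config}}.
#' @param plan a \code{\link{make_cv_plan}} result.
#' @param scorer optional function(Z, Y_train, config) returning a
#'   \code{score_matrix}; defaults to \code{\link{run_pipeline}}. Useful for
#'   baselines and for testing the CV machinery with an oracle predictor.
#' @return a list of class \code{cv_result}: \code{per_fold} data frame
#'   (repeat, fold, auc, aupr), \code{per_repeat} means, and \code{summary}
#'   with grand means and standard deviations across repeats.
#' @export
run_cv <- function(Z, Y, config = training_config(), plan, scorer = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  if (is.null(scorer))
    scorer <- function(Z, Y_train, cfg) run_pipeline(Z, Y_train, cfg)
  rows <- vector("list", plan$n_repeats * plan$n_folds)
  i <- 0L
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      i <- i + 1L
      Y_train <- mask_training_matrix(Y, plan, f, r)
      cfg <- config
      cfg$seed <- derive_seed(config$seed, "cv", r, f)
      scores <- scorer(Z, Y_train, cfg)
      cells <- held_out_cells(plan, f, r)
      if (plan$scenario == "pairwise" && plan$positives_only) {
        # held-out positives vs every zero pair of Y
        cells <- union(cells, which(Y$values == 0))
      }
      labs <- Y$values[cells]
      sc <- scores$values[cells]
      if (length(unique(labs)) < 2L) {
        warning(sprintf("repeat %d fold %d: single-class test set, recorded as NA",
                        r, f))
        auc <- NA_real_; aupr <- NA_real_
      } else {
        auc <- auc_score(labs, sc)
        aupr <- aupr_score(labs, sc)
      }
      rows[[i]] <- data.frame(repeat_idx = r, fold = f, auc = auc,
                              aupr = aupr)
    }
  }
  per_fold <- do.call(rbind, rows)
  per_repeat <- do.call(rbind, lapply(split(per_fold, per_fold$repeat_idx),
    function(d) data.frame(repeat_idx = d$repeat_idx[1L],
                           auc = mean(d$auc, na.rm = TRUE),
                           aupr = mean(d$aupr, na.rm = TRUE))))
  rownames(per_repeat) <- NULL
  summ <- list(auc_mean = mean(per_repeat$auc),
               auc_sd = stats::sd(per_repeat$auc),
               aupr_mean = mean(per_repeat$aupr),
               aupr_sd = stats::sd(per_repeat$aupr))
  structure(list(per_fold = per_fold, per_repeat = per_repeat,
                 summary = summ, scenario = plan$scenario),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: AUC %.3f (sd %.3f), AUPR %.3f (sd %.3f) over %d repeats\n",
              x$scenario, x$summary$auc_mean, x$summary$auc_sd,
              x$summary$aupr_mean, x$summary$aupr_sd, nrow(x$per_repeat)))
  invisible(x)
}
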