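#' Training configuration for the denoising autoencoder
#'
#' Defaults follow the published settings where the source method states
#' them: two hidden layers of (15, 5) units with sigmoid activations in every
#' layer, minibatch size 100, loss weights alpha = 0.4 (corrupted/prediction
#' term) and beta = 0.6 (uncorrupted/reconstruction term), L2 strength
#' lambda = 10 (use 1 for the small nuclear-receptor benchmark). Learning
#' rate, epoch count and corruption rate are not published; the defaults here
#' (0.1, 200, 0.2) are package choices, documented as such.
#'
#' @param alpha weight of the corrupted-position error term, in (0,1).
#' @param beta weight of the uncorrupted-position error term, in (0,1).
#' @param lambda_reg L2 regularization strength, >= 0.
#' @param corruption_rate fraction of observed input positions masked to zero
#'   per sample, in [0,1).
#' @param hidden_sizes integer vector of encoder widths; the last entry is
#'   the bottleneck. The decoder mirrors them.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training samples.
#' @param learning_rate constant step size for plain minibatch gradient
#'   descent.
#' @param seed integer seed governing initialization, shuffling and
#'   corruption.
#' @param zeros_are_observed if \code{TRUE}, every position of a training
#'   sample is treated as known; the default (\code{FALSE}) treats only the
#'   ones of the binary input as known, zeros as missing (input-zeroed and
#'   error-zeroed).
#' @param regularize_biases include bias vectors in the L2 penalty
#'   (off by default; conventional).
#' @return a validated list of class \code{training_config}.
#' @export
training_config <- function(alpha = 0.4, beta = 0.6, lambda_reg = 10,
                            corruption_rate = 0.2, hidden_sizes = c(15L, 5L),
                            batch_size = 100L, epochs = 200L,
                            learning_rate = 0.1, seed = 1L,
                            zeros_are_observed = FALSE,
                            regularize_biases = FALSE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)")
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0,1)")
  if (lambda_reg < 0) stop("lambda_reg must be >= 0")
  if (!(corruption_rate >= 0 && corruption_rate < 1))
    stop("corruption_rate must lie in [0,1)")
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L))
    stop("hidden_sizes must be positive integers")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(alpha = alpha, beta = beta, lambda_reg = lambda_reg,
                 corruption_rate = corruption_rate,
                 hidden_sizes = hidden_sizes,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 zeros_are_observed = isTRUE(zeros_are_observed),
                 regularize_biases = isTRUE(regularize_biases)),
            class = "training_config")
}

#' Initialize autoencoder parameters
#'
#' Encoder maps input_dim -> hidden_sizes[1] -> ... -> bottleneck; the
#' decoder mirrors the widths back to input_dim. Weights are drawn uniformly
#' in +/- 1/sqrt(fan_in) (scale-stable for sigmoid layers), biases start at
#' zero. Weight matrices are stored fan_in x fan_out.
#'
#' @param input_dim length of one training sample (fingerprint length f).
#' @param hidden_sizes encoder widths, last entry the bottleneck.
#' @param seed integer seed (set immediately before drawing).
#' @return a list of class \code{autoencoder_params} with fields
#'   \code{encoder_weights}, \code{encoder_biases}, \code{decoder_weights},
#'   \code{decoder_biases}.
#' @export
init_params <- function(input_dim, hidden_sizes = c(15L, 5L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  enc_dims <- c(input_dim, hidden_sizes)
  dec_dims <- rev(enc_dims)
  draw <- function(fan_in, fan_out) {
    lim <- 1 / sqrt(fan_in)
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  mk <- function(dims) {
    ws <- vector("list", length(dims) - 1L)
    bs <- vector("list", length(dims) - 1L)
    for (l in seq_along(ws)) {
      ws[[l]] <- draw(dims[l], dims[l + 1L])
      bs[[l]] <- numeric(dims[l + 1L])
    }
    list(w = ws, b = bs)
  }
  e <- mk(enc_dims); d <- mk(dec_dims)
  structure(list(encoder_weights = e$w, encoder_biases = e$b,
                 decoder_weights = d$w, decoder_biases = d$b),
            class = "autoencoder_params")
}

# stack encoder+decoder into one layer list for forward/backward passes
all_layers <- function(params) {
  list(w = c(params$encoder_weights, params$decoder_weights),
       b = c(params$encoder_biases, params$decoder_biases))
}

# forward pass keeping every activation; X is input_dim x batch
forward_pass <- function(X, params) {
  ly <- all_layers(params)
  acts <- vector("list", length(ly$w) + 1L)
  acts[[1L]] <- X
  for (l in seq_along(ly$w)) {
    acts[[l + 1L]] <- sigmoid(crossprod(ly$w[[l]], acts[[l]]) + ly$b[[l]])
  }
  acts
}

#' Encode inputs to the bottleneck representation
#'
#' Each encoder layer applies sigmoid(t(V) x + b); outputs lie in (0,1).
#'
#' @param x length-f vector or f x batch matrix.
#' @param params an \code{\link{autoencoder_params}}.
#' @return bottleneck vector (or bottleneck x batch matrix).
#' @export
encode <- function(x, params) {
  vec <- is.null(dim(x))
  A <- if (vec) matrix(x, ncol = 1L) else x
  if (nrow(A) != nrow(params$encoder_weights[[1L]]))
    stop("input length does not match encoder input dimension")
  for (l in seq_along(params$encoder_weights)) {
    A <- sigmoid(crossprod(params$encoder_weights[[l]], A) +
                   params$encoder_biases[[l]])
  }
  if (vec) drop(A) else A
}

#' Decode a bottleneck representation back to input space
#'
#' Mirror of \code{\link{encode}}; the output layer is also sigmoid, so
#' reconstructions lie in (0,1).
#'
#' @param h bottleneck vector or bottleneck x batch matrix.
#' @param params an \code{\link{autoencoder_params}}.
#' @return length-f vector (or f x batch matrix).
#' @export
decode <- function(h, params) {
  vec <- is.null(dim(h))
  A <- if (vec) matrix(h, ncol = 1L) else h
  if (nrow(A) != nrow(params$decoder_weights[[1L]]))
    stop("input length does not match decoder input dimension")
  for (l in seq_along(params$decoder_weights)) {
    A <- sigmoid(crossprod(params$decoder_weights[[l]], A) +
                   params$decoder_biases[[l]])
  }
  if (vec) drop(A) else A
}

#' Mask a random fraction of the observed input positions
#'
#' Corruption draws a uniformly random subset C of the observed positions
#' (each observed position is included independently with probability
#' \code{rate}, so |C| is binomial with mean rate * n_observed) and zeroes
#' them. Unobserved positions are assigned zero on the input edges -- they
#' carry no information -- and never enter C. Randomness comes from R's
#' global generator; seed it for reproducibility.
#'
#' @param x numeric input vector.
#' @param observed_mask logical vector marking known positions.
#' @param rate corruption rate in [0,1).
#' @return a list of class \code{corruption_record} with
#'   \code{corrupted_input} and \code{corrupted_index_set}.
#' @export
corrupt <- function(x, observed_mask, rate) {
  stopifnot(length(x) == length(observed_mask), rate >= 0, rate < 1)
  obs <- which(observed_mask)
  C <- integer(0)
  if (rate > 0 && length(obs) > 0L) {
    C <- obs[stats::runif(length(obs)) < rate]
  }
  xt <- x
  xt[!observed_mask] <- 0
  xt[C] <- 0
  structure(list(corrupted_input = xt, corrupted_index_set = C),
            class = "corruption_record")
}

# per-position loss weights: alpha on corrupted observed positions, beta on
# uncorrupted observed positions, zero on unobserved ones
position_weights <- function(n, corrupted_idx, observed_mask, config) {
  w <- numeric(n)
  w[observed_mask] <- config$beta
  w[intersect(corrupted_idx, which(observed_mask))] <- config$alpha
  w
}

l2_penalty <- function(params, config) {
  if (config$lambda_reg == 0) return(0)
  s <- sum(vapply(params$encoder_weights, function(w) sum(w^2), 0)) +
    sum(vapply(params$decoder_weights, function(w) sum(w^2), 0))
  if (config$regularize_biases) {
    s <- s + sum(vapply(params$encoder_biases, function(b) sum(b^2), 0)) +
      sum(vapply(params$decoder_biases, function(b) sum(b^2), 0))
  }
  config$lambda_reg / 2 * s
}

#' Masked, reweighted denoising reconstruction loss
#'
#' alpha * sum over corrupted observed positions of (x_j - nn(x~)_j)^2 +
#' beta * sum over uncorrupted observed positions + lambda/2 * sum of squared
#' weight norms. Unobserved positions contribute nothing: their error is
#' discarded, equivalent to removing those output neurons.
#'
#' @param x clean target vector.
#' @param record a \code{\link{corrupt}} result for \code{x}.
#' @param reconstruction network output \code{nn(x~)}.
#' @param observed_mask logical vector of known positions.
#' @param config a \code{\link{training_config}}.
#' @param params an \code{\link{autoencoder_params}} (for the L2 term).
#' @return scalar loss.
#' @export
masked_denoising_loss <- function(x, record, reconstruction, observed_mask,
                                  config, params) {
  stopifnot(length(x) == length(reconstruction),
            length(x) == length(observed_mask))
  w <- position_weights(length(x), record$corrupted_index_set,
                        observed_mask, config)
  sum(w * (x - reconstruction)^2) + l2_penalty(params, config)
}

#' Exact gradient of the masked denoising loss
#'
#' Backpropagates the reweighted squared error from the observed positions
#' only; unobserved positions inject zero error (their back-propagated values
#' are replaced by zero). The L2 term contributes lambda * weights (and
#' lambda * biases when bias regularization is on).
#'
#' @inheritParams masked_denoising_loss
#' @return a list shaped like \code{params} holding the gradients.
#' @export
loss_gradient <- function(x, record, observed_mask, config, params) {
  n_enc <- length(params$encoder_weights)
  acts <- forward_pass(matrix(record$corrupted_input, ncol = 1L), params)
  ly <- all_layers(params)
  L <- length(ly$w)
  recon <- acts[[L + 1L]]
  w <- position_weights(length(x), record$corrupted_index_set,
                        observed_mask, config)
  gw <- vector("list", L)
  gb <- vector("list", L)
  # output delta: d/ds of sum w_j (x_j - sigmoid(s_j))^2
  delta <- (2 * w * (drop(recon) - x)) * drop(recon * (1 - recon))
  delta <- matrix(delta, ncol = 1L)
  for (l in L:1) {
    gw[[l]] <- acts[[l]] %*% t(delta)
    gb[[l]] <- rowSums(delta)
    if (l > 1L) {
      A <- acts[[l]]
      delta <- (ly$w[[l]] %*% delta) * (A * (1 - A))
    }
  }
  out <- list(encoder_weights = gw[seq_len(n_enc)],
              encoder_biases = gb[seq_len(n_enc)],
              decoder_weights = gw[(n_enc + 1L):L],
              decoder_biases = gb[(n_enc + 1L):L])
  if (config$lambda_reg > 0) {
    for (l in seq_len(n_enc)) {
      out$encoder_weights[[l]] <- out$encoder_weights[[l]] +
        config$lambda_reg * params$encoder_weights[[l]]
      if (config$regularize_biases)
        out$encoder_biases[[l]] <- out$encoder_biases[[l]] +
          config$lambda_reg * params$encoder_biases[[l]]
    }
    for (l in seq_along(params$decoder_weights)) {
      out$decoder_weights[[l]] <- out$decoder_weights[[l]] +
        config$lambda_reg * params$decoder_weights[[l]]
      if (config$regularize_biases)
        out$decoder_biases[[l]] <- out$decoder_biases[[l]] +
          config$lambda_reg * params$decoder_biases[[l]]
    }
  }
  out
}

# batched gradient of the mean per-sample data loss over a minibatch, plus
# one regularizer contribution. X, Xcorr: input_dim x b; Wobs, Wpos: weights
# per position per sample (alpha/beta/0 pattern).
batch_gradient <- function(X, Xcorr, Wpos, config, params) {
  b <- ncol(X)
  acts <- forward_pass(Xcorr, params)
  ly <- all_layers(params)
  L <- length(ly$w)
  recon <- acts[[L + 1L]]
  delta <- (2 * Wpos * (recon - X)) * (recon * (1 - recon)) / b
  gw <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gw[[l]] <- acts[[l]] %*% t(delta)
    gb[[l]] <- rowSums(delta)
    if (l > 1L) {
      A <- acts[[l]]
      delta <- (ly$w[[l]] %*% delta) * (A * (1 - A))
    }
  }
  data_loss <- sum(Wpos * (X - recon)^2)
  list(gw = gw, gb = gb, data_loss = data_loss)
}

#' Train the denoising autoencoder on a binary fingerprint-target matrix
#'
#' Each target -- a column of W, a length-f fingerprint profile -- is one
#' training sample. Under the default \code{zeros_are_observed = FALSE},
#' positions equal to 1 are the known interactions; zeros are missing and
#' contribute neither input signal nor error. Training is plain minibatch
#' gradient descent with a constant learning rate on the masked,
#' alpha/beta-reweighted denoising loss with L2 regularization. The epoch
#' loss trace is attached as \code{attr(params, "loss_history")}.
#'
#' @param W a binary-stage \code{\link{fingerprint_target_matrix}}, or a
#'   plain binary matrix whose columns are samples.
#' @param config a \code{\link{training_config}}.
#' @return trained \code{\link{autoencoder_params}} with a
#'   \code{loss_history} attribute (one mean loss per epoch).
#' @export
train_autoencoder <- function(W, config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  M <- if (inherits(W, "fingerprint_target_matrix")) {
    if (W$stage != "binary") stop("train_autoencoder expects the binary stage")
    W$values
  } else as.matrix(W)
  check_binary(M, "training matrix")
  if (sum(M) == 0)
    stop("no observed interactions: the training matrix is all zeros")
  f <- nrow(M); m <- ncol(M)
  set.seed(config$seed)
  params <- init_params(f, config$hidden_sizes)
  obs <- if (config$zeros_are_observed) matrix(TRUE, f, m) else M == 1
  lam <- config$lambda_reg
  lr <- config$learning_rate
  n_enc <- length(params$encoder_weights)
  loss_hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(m)
    ep_data_loss <- 0
    for (start in seq(1L, m, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, m)]
      X <- M[, idx, drop = FALSE]
      O <- obs[, idx, drop = FALSE]
      # corrupt: each observed position masked independently at the rate
      Cm <- O & (matrix(stats::runif(length(X)), f) < config$corruption_rate)
      Xc <- X; Xc[Cm] <- 0
      Wpos <- matrix(0, f, length(idx))
      Wpos[O] <- config$beta
      Wpos[Cm] <- config$alpha
      g <- batch_gradient(X, Xc, Wpos, config, params)
      for (l in seq_len(n_enc)) {
        gradw <- g$gw[[l]] + lam * params$encoder_weights[[l]]
        params$encoder_weights[[l]] <- params$encoder_weights[[l]] - lr * gradw
        gradb <- g$gb[[l]] + if (config$regularize_biases)
          lam * params$encoder_biases[[l]] else 0
        params$encoder_biases[[l]] <- params$encoder_biases[[l]] - lr * gradb
      }
      for (l in seq_along(params$decoder_weights)) {
        k <- n_enc + l
        gradw <- g$gw[[k]] + lam * params$decoder_weights[[l]]
        params$decoder_weights[[l]] <- params$decoder_weights[[l]] - lr * gradw
        gradb <- g$gb[[k]] + if (config$regularize_biases)
          lam * params$decoder_biases[[l]] else 0
        params$decoder_biases[[l]] <- params$decoder_biases[[l]] - lr * gradb
      }
      ep_data_loss <- ep_data_loss + g$data_loss
    }
    loss_hist[ep] <- ep_data_loss / m + l2_penalty(params, config)
    if (!is.finite(loss_hist[ep]))
      stop(sprintf("training diverged at epoch %d (non-finite loss); lower the learning rate",
                   ep))
  }
  attr(params, "loss_history") <- loss_hist
  params
}

#' Train the drug-profile variant directly on the interaction matrix
#'
#' Ablation without the fingerprint densification: rows of Y (drug
#' interaction profiles over the m targets) are the training samples, so the
#' network embeds drugs rather than targets and the reconstruction itself is
#' the score matrix.
#'
#' @param Y an \code{\link{interaction_matrix}}.
#' @param config a \code{\link{training_config}}.
#' @return trained \code{\link{autoencoder_params}} over input dimension m.
#' @export
train_drug_autoencoder <- function(Y, config = training_config()) {
  stopifnot(inherits(Y, "interaction_matrix"))
  train_autoencoder(t(Y$values), config)
}

#' Reconstruct a matrix through the trained autoencoder
#'
#' Uncorrupted forward pass, one column at a time (vectorized): column t of
#' the result is decode(encode(W[, t])). All entries lie in (0,1).
#'
#' @param W binary-stage \code{\link{fingerprint_target_matrix}} or plain
#'   matrix with f rows.
#' @param params trained \code{\link{autoencoder_params}}.
#' @return f x m numeric matrix of reconstructions.
#' @export
reconstruct <- function(W, params) {
  M <- if (inherits(W, "fingerprint_target_matrix")) W$values else as.matrix(W)
  if (nrow(M) != nrow(params$encoder_weights[[1L]]))
    stop("matrix row count does not match the trained input dimension")
  out <- decode(encode(M, params), params)
  dimnames(out) <- dimnames(M)
  out
}
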