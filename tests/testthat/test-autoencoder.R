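test_that("training_config validates its ranges", {
  cfg <- training_config()
  expect_equal(cfg$alpha, 0.4)
  expect_equal(cfg$beta, 0.6)
  expect_equal(cfg$hidden_sizes, c(15L, 5L))
  expect_equal(cfg$batch_size, 100L)
  expect_equal(cfg$lambda_reg, 10)
  expect_error(training_config(alpha = 1.5), "alpha")
  expect_error(training_config(beta = 0), "beta")
  expect_error(training_config(corruption_rate = 1), "corruption_rate")
  expect_error(training_config(lambda_reg = -1), "lambda_reg")
  expect_error(training_config(learning_rate = 0), "learning_rate")
})

test_that("encode/decode match the forward oracle and saturate correctly", {
  # zero parameters: sigmoid(0) = 0.5 at every unit
  p0 <- init_params(6, c(4, 2), seed = 1)
  for (fld in c("encoder_weights", "decoder_weights"))
    p0[[fld]] <- lapply(p0[[fld]], function(w) w * 0)
  x <- rnorm(6)
  expect_equal(encode(x, p0), rep(0.5, 2))
  expect_equal(decode(encode(x, p0), p0), rep(0.5, 6))

  # saturation: large negative bias drives the output to ~0
  p1 <- init_params(1, 1, seed = 2)
  p1$encoder_weights[[1]][] <- 0
  p1$encoder_biases[[1]][] <- -30
  expect_lt(encode(0.7, p1), 1e-12)

  # random params/input against the independent loop oracle
  for (seed in 1:5) {
    p <- random_params(7, c(4, 2), seed)
    set.seed(seed + 100)
    x <- rnorm(7)
    full <- decode(encode(x, p), p)
    expect_equal(full, oracle_forward(x, p), tolerance = 1e-12)
  }
  expect_error(encode(rnorm(5), p0), "length")
})

test_that("corrupt masks a binomial fraction of observed positions only", {
  x <- c(1, 0, 1, 1, 0)
  obs <- x == 1
  set.seed(1)
  rec <- corrupt(x, obs, 0)
  expect_length(rec$corrupted_index_set, 0)
  expect_identical(rec$corrupted_input, x)

  # all-unobserved input: C stays empty at any rate
  rec <- corrupt(c(0, 0, 0), c(FALSE, FALSE, FALSE), 0.9)
  expect_length(rec$corrupted_index_set, 0)

  # |C| within central binomial 99% bounds at rate 0.5 on 1000 observed
  x1000 <- rep(1, 1000)
  set.seed(42)
  rec <- corrupt(x1000, rep(TRUE, 1000), 0.5)
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(length(rec$corrupted_index_set), bounds[1])
  expect_lte(length(rec$corrupted_index_set), bounds[2])
  expect_true(all(rec$corrupted_input[rec$corrupted_index_set] == 0))
  untouched <- setdiff(seq_along(x1000), rec$corrupted_index_set)
  expect_identical(rec$corrupted_input[untouched], x1000[untouched])
})

test_that("masked loss equals the per-position loop oracle", {
  # single-term arithmetic case: alpha * 1
  cfg <- training_config(alpha = 0.4, beta = 0.6, lambda_reg = 0)
  p <- init_params(3, 2, seed = 1)
  rec <- structure(list(corrupted_input = c(0, 0, 1),
                        corrupted_index_set = 1L),
                   class = "corruption_record")
  loss <- masked_denoising_loss(c(1, 0, 1), rec, c(0, 0, 1),
                                rep(TRUE, 3), cfg, p)
  expect_equal(loss, 0.4)

  # perfect reconstruction, lambda 0 -> zero loss
  expect_equal(masked_denoising_loss(c(1, 0, 1), rec, c(1, 0, 1),
                                     rep(TRUE, 3), cfg, p), 0)

  # random instances against the loop oracle, with regularizer
  for (seed in 1:20) {
    set.seed(seed)
    f <- sample(3:10, 1)
    p <- random_params(f, c(4, 2), seed)
    cfg <- training_config(alpha = runif(1, 0.1, 0.9),
                           beta = runif(1, 0.1, 0.9),
                           lambda_reg = runif(1, 0, 2))
    x <- rbinom(f, 1, 0.6)
    obs <- if (runif(1) < 0.5) x == 1 else rep(TRUE, f)
    rec <- corrupt(x, obs, 0.4)
    recon <- oracle_forward(rec$corrupted_input, p)
    expect_equal(
      masked_denoising_loss(x, rec, recon, obs, cfg, p),
      oracle_loss(x, rec$corrupted_index_set, recon, obs, cfg, p),
      tolerance = 1e-12)
  }
})

test_that("loss_gradient matches central finite differences", {
  worst <- 0
  for (seed in 1:20) {
    set.seed(seed)
    f <- sample(3:10, 1)
    p <- random_params(f, c(4, 2), seed + 500)
    cfg <- training_config(alpha = runif(1, 0.2, 0.8),
                           beta = runif(1, 0.2, 0.8),
                           lambda_reg = sample(c(0, 0.5, 2), 1))
    x <- rbinom(f, 1, 0.6)
    obs <- if (runif(1) < 0.5) x == 1 else rep(TRUE, f)
    rec <- corrupt(x, obs, 0.3)
    g <- loss_gradient(x, rec, obs, cfg, p)
    gn <- oracle_numeric_gradient(x, rec, obs, cfg, p)
    for (fld in names(gn)) for (l in seq_along(gn[[fld]])) {
      err <- rel_err(g[[fld]][[l]], gn[[fld]][[l]])
      worst <- max(worst, err)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient degenerate cases: no observations, regularizer-only", {
  f <- 6
  p <- random_params(f, c(3, 2), 9)
  # all unobserved, lambda 0 -> zero gradient everywhere
  cfg0 <- training_config(lambda_reg = 0)
  rec <- corrupt(rep(0, f), rep(FALSE, f), 0.5)
  g <- loss_gradient(rep(0, f), rec, rep(FALSE, f), cfg0, p)
  for (fld in names(g)) for (l in seq_along(g[[fld]]))
    expect_equal(max(abs(g[[fld]][[l]])), 0)

  # zero data error (nothing observed), lambda > 0 -> gradient is
  # lambda * weights on weights, zero on biases
  cfg1 <- training_config(lambda_reg = 3)
  g1 <- loss_gradient(rep(0, f), rec, rep(FALSE, f), cfg1, p)
  for (l in seq_along(p$encoder_weights))
    expect_equal(g1$encoder_weights[[l]], 3 * p$encoder_weights[[l]])
  for (l in seq_along(p$decoder_weights))
    expect_equal(g1$decoder_weights[[l]], 3 * p$decoder_weights[[l]])
  for (l in seq_along(g1$encoder_biases))
    expect_equal(max(abs(g1$encoder_biases[[l]])), 0)
})

test_that("masking: unobserved positions never touch loss or gradient", {
  set.seed(77)
  f <- 8
  p <- random_params(f, c(4, 2), 3)
  cfg <- training_config(lambda_reg = 0)
  x <- c(1, 1, 0, 1, 0, 0, 1, 0)
  obs <- x == 1
  set.seed(5); rec <- corrupt(x, obs, 0.3)
  base_recon <- oracle_forward(rec$corrupted_input, p)
  base_loss <- masked_denoising_loss(x, rec, base_recon, obs, cfg, p)
  base_grad <- loss_gradient(x, rec, obs, cfg, p)
  for (j in which(!obs)) {
    # perturb the TARGET at an unobserved position: loss and gradient as-is
    x2 <- x; x2[j] <- x2[j] + rnorm(1)
    expect_equal(masked_denoising_loss(x2, rec, base_recon, obs, cfg, p),
                 base_loss)
    g2 <- loss_gradient(x2, rec, obs, cfg, p)
    expect_equal(g2, base_grad)
  }
})

test_that("alpha == beta collapses to uniformly weighted masked MSE", {
  set.seed(13)
  f <- 9
  p <- random_params(f, c(4, 2), 21)
  cfg <- training_config(alpha = 0.5, beta = 0.5, lambda_reg = 1.3)
  x <- rbinom(f, 1, 0.5)
  obs <- x == 1
  rec <- corrupt(x, obs, 0.4)
  recon <- oracle_forward(rec$corrupted_input, p)
  wsq <- sum(vapply(c(p$encoder_weights, p$decoder_weights),
                    function(w) sum(w^2), 0))
  closed_form <- 0.5 * sum(((x - recon)^2)[obs]) + 1.3 / 2 * wsq
  expect_equal(masked_denoising_loss(x, rec, recon, obs, cfg, p),
               closed_form, tolerance = 1e-12)
})

test_that("training reduces reconstruction error and is seed-deterministic", {
  # single sample, no corruption: optimization sanity
  w1 <- matrix(c(1, 0, 1, 1, 0, 1), 6, 1)
  cfg <- training_config(hidden_sizes = c(4, 2), lambda_reg = 0,
                         corruption_rate = 0, epochs = 300, seed = 2,
                         batch_size = 1)
  set.seed(cfg$seed)
  p_init <- init_params(6, cfg$hidden_sizes)
  err0 <- sum(((w1 - reconstruct(w1, p_init))^2)[w1 == 1])
  p <- train_autoencoder(w1, cfg)
  err1 <- sum(((w1 - reconstruct(w1, p))^2)[w1 == 1])
  expect_lt(err1, err0)

  # loss trend on a synthetic fixture: final mean < initial mean
  ds <- generate_synthetic(synthetic_spec(n_drugs = 30, n_targets = 40,
                                          n_bits = 60, seed = 6,
                                          interaction_density = 0.1))
  W <- preprocess(ds$Z, ds$Y)
  cfg <- training_config(lambda_reg = 1, epochs = 100, seed = 3)
  pa <- train_autoencoder(W, cfg)
  lh <- attr(pa, "loss_history")
  k <- max(1, round(length(lh) * 0.1))
  expect_lt(mean(tail(lh, k)), mean(head(lh, k)))

  # bit-reproducibility under a fixed seed
  pb <- train_autoencoder(W, cfg)
  attr(pa, "loss_history") <- NULL; attr(pb, "loss_history") <- NULL
  expect_identical(pa, pb)
})

test_that("train rejects an all-zero matrix and divergent runs abort", {
  expect_error(train_autoencoder(matrix(0, 4, 3)), "no observed")
  expect_error(train_autoencoder(matrix(c(1, 2), 2, 1),
                                 training_config()), "0/1")
})

test_that("reconstruct is the uncorrupted forward pass per column", {
  ds <- generate_synthetic(synthetic_spec(n_drugs = 10, n_targets = 8,
                                          n_bits = 15, seed = 12))
  W <- preprocess(ds$Z, ds$Y)
  p <- random_params(15, c(6, 3), 31)
  R <- reconstruct(W, p)
  expect_true(all(R > 0 & R < 1))
  for (t in c(1, 4, 8))
    expect_equal(R[, t], oracle_forward(W$values[, t], p),
                 ignore_attr = TRUE, tolerance = 1e-12)
  # zero params -> all 0.5
  p0 <- p
  for (fld in c("encoder_weights", "decoder_weights"))
    p0[[fld]] <- lapply(p0[[fld]], function(w) w * 0)
  p0$encoder_biases <- lapply(p0$encoder_biases, function(b) b * 0)
  p0$decoder_biases <- lapply(p0$decoder_biases, function(b) b * 0)
  expect_equal(unname(reconstruct(W, p0)),
               matrix(0.5, nrow(W$values), ncol(W$values)))
  expect_error(reconstruct(matrix(0, 3, 2), p), "dimension")
})

test_that("the drug-profile variant trains on rows of Y", {
  ds <- generate_synthetic(synthetic_spec(n_drugs = 20, n_targets = 12,
                                          n_bits = 30, seed = 14,
                                          interaction_density = 0.15))
  cfg <- training_config(hidden_sizes = c(6, 3), lambda_reg = 1,
                         epochs = 50, seed = 4)
  p <- train_drug_autoencoder(ds$Y, cfg)
  # input dimension is the number of targets
  expect_equal(nrow(p$encoder_weights[[1]]), 12)
  scores <- reconstruct(t(ds$Y$values), p)
  expect_true(all(is.finite(scores)))
})
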