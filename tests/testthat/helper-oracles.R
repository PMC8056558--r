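# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (loops, enumeration, finite differences) kept free of the
# package's own code paths.

# plain-loop forward pass: sigmoid(t(W) a + b) layer by layer
oracle_forward <- function(x, params) {
  a <- x
  ws <- c(params$encoder_weights, params$decoder_weights)
  bs <- c(params$encoder_biases, params$decoder_biases)
  for (l in seq_along(ws)) a <- 1 / (1 + exp(-(t(ws[[l]]) %*% a + bs[[l]])))
  drop(a)
}

# per-position loop for the masked alpha/beta loss
oracle_loss <- function(x, corrupted_idx, recon, observed, config, params) {
  total <- 0
  for (j in seq_along(x)) {
    if (!observed[j]) next
    w <- if (j %in% corrupted_idx) config$alpha else config$beta
    total <- total + w * (x[j] - recon[j])^2
  }
  reg <- 0
  for (W in c(params$encoder_weights, params$decoder_weights))
    reg <- reg + sum(W^2)
  if (config$regularize_biases)
    for (b in c(params$encoder_biases, params$decoder_biases))
      reg <- reg + sum(b^2)
  total + config$lambda_reg / 2 * reg
}

# central finite differences of masked_denoising_loss over every parameter
oracle_numeric_gradient <- function(x, record, observed, config, params,
                                    h = 1e-5) {
  loss_at <- function(p) {
    recon <- oracle_forward(record$corrupted_input, p)
    oracle_loss(x, record$corrupted_index_set, recon, observed, config, p)
  }
  perturb_field <- function(field) {
    lapply(seq_along(params[[field]]), function(l) {
      g <- params[[field]][[l]]
      g[] <- 0
      for (i in seq_along(g)) {
        pp <- params; pp[[field]][[l]][i] <- pp[[field]][[l]][i] + h
        pm <- params; pm[[field]][[l]][i] <- pm[[field]][[l]][i] - h
        g[i] <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      }
      g
    })
  }
  list(encoder_weights = perturb_field("encoder_weights"),
       encoder_biases = perturb_field("encoder_biases"),
       decoder_weights = perturb_field("decoder_weights"),
       decoder_biases = perturb_field("decoder_biases"))
}

# exhaustive positive/negative pair count, ties as 1/2
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# threshold sweep over unique scores, step-wise area
oracle_aupr <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_rec <- 0; area <- 0
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# existential densification rule: W[k, t] = 1 iff some drug carries bit k and
# hits target t
oracle_preprocess <- function(Zv, Yv) {
  f <- nrow(Zv); n <- ncol(Zv); m <- ncol(Yv)
  W <- matrix(0, f, m)
  for (k in seq_len(f)) for (t in seq_len(m)) for (d in seq_len(n)) {
    if (Zv[k, d] == 1 && Yv[d, t] == 1) { W[k, t] <- 1; break }
  }
  W
}

rel_err <- function(a, b) {
  num <- sqrt(sum((a - b)^2))
  den <- max(1e-8, sqrt(sum(a^2)) + sqrt(sum(b^2)))
  num / den
}

random_params <- function(f, hidden, seed) {
  set.seed(seed)
  p <- init_params(f, hidden)
  # non-zero biases so bias gradients are exercised away from zero
  p$encoder_biases <- lapply(p$encoder_biases, function(b) stats::rnorm(length(b), sd = 0.3))
  p$decoder_biases <- lapply(p$decoder_biases, function(b) stats::rnorm(length(b), sd = 0.3))
  p
}

tiny_interaction_file <- function(values, drug_ids, target_ids,
                                  path = tempfile(fileext = ".tsv")) {
  lines <- c(paste(c("id", target_ids), collapse = "\t"),
             vapply(seq_along(drug_ids), function(i)
               paste(c(drug_ids[i], values[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  path
}
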