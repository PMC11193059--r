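# Shared fixtures and independent oracles for the test suite.

# reduced architecture used wherever a model must actually train: small
# enough that a full training run takes seconds to a couple of minutes
small_config <- function(...) {
  args <- utils::modifyList(
    list(embed_dim = 16L, kernel_sizes = c(1L, 3L),
         filter_counts = c(8L, 8L), num_heads = 2L, num_layers = 2L,
         protein_length = 48L, smiles_length = 24L, fc_hidden = c(32L)),
    list(...))
  do.call(dta_config, args)
}

# --- independent oracles (never call package internals) -----------------

oracle_rmse <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - p[i])^2
  sqrt(s / length(y))
}

oracle_mae <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + abs(y[i] - p[i])
  s / length(y)
}

oracle_ci <- function(y, p) {
  num <- 0; z <- 0
  for (i in seq_along(y)) for (j in seq_along(y)) {
    if (y[i] > y[j]) {
      z <- z + 1
      if (p[i] > p[j]) num <- num + 1
      else if (p[i] == p[j]) num <- num + 0.5
    }
  }
  num / z
}

oracle_pearson <- function(y, p) {
  ym <- mean(y); pm <- mean(p)
  num <- sum((y - ym) * (p - pm))
  num / sqrt(sum((y - ym)^2) * sum((p - pm)^2))
}

oracle_sd <- function(y, p) {
  # closed-form least squares y ~ a*p + b via normal equations
  n <- length(y)
  a <- (n * sum(p * y) - sum(p) * sum(y)) / (n * sum(p^2) - sum(p)^2)
  b <- (sum(y) - a * sum(p)) / n
  sqrt(sum((y - (a * p + b))^2) / (n - 1))
}

oracle_attention <- function(Q, K, V) {
  L <- nrow(Q); d <- ncol(Q)
  S <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(d)
  }
  A <- matrix(0, L, L)
  for (i in seq_len(L)) A[i, ] <- exp(S[i, ]) / sum(exp(S[i, ]))
  A %*% V
}

# independently coded AdamW scalar transcript
oracle_adamw_trajectory <- function(x0, grads, alpha, beta1 = 0.9,
                                    beta2 = 0.999, eps = 1e-8,
                                    lambda = 0, eta = 1) {
  x <- x0; v <- 0; s <- 0
  out <- numeric(length(grads))
  for (t in seq_along(grads)) {
    g <- grads[t]
    v <- beta1 * v + (1 - beta1) * g
    s <- beta2 * s + (1 - beta2) * g^2
    vhat <- v / (1 - beta1^t)
    shat <- s / (1 - beta2^t)
    x <- x - eta * (alpha * vhat / (sqrt(shat) + eps) + lambda * x)
    out[t] <- x
  }
  out
}

# --- shared trained models (expensive; built once per test run) ---------

.model_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.model_cache[[key]])) .model_cache[[key]] <- builder()
  .model_cache[[key]]
}

signal_dataset <- function(seed = 1L) {
  cached(paste0("ds", seed), function() {
    generate_dataset(synthetic_spec(n_records = 200L, noise_sd = 0.1,
                                    seed = seed))
  })
}

trained_v1 <- function(seed = 1L) {
  cached(paste0("v1-", seed), function() {
    ds <- signal_dataset(seed)
    m <- new_dta_model(small_config(), seed = seed)
    train_dta(m, ds[1:160, ], epochs = 120L, batch_size = 16L, lr = 1e-3,
              weight_decay = 1e-4, seed = seed)
  })
}

trained_permuted <- function(seed = 1L) {
  cached(paste0("perm-", seed), function() {
    ds <- signal_dataset(seed)[1:160, ]
    set.seed(seed + 1000L)
    ds$affinity <- sample(ds$affinity)
    m <- new_dta_model(small_config(), seed = seed)
    train_dta(m, ds, epochs = 120L, batch_size = 16L, lr = 1e-3,
              weight_decay = 1e-4, seed = seed)
  })
}

trained_v2 <- function(seed = 1L) {
  cached(paste0("v2-", seed), function() {
    ds <- signal_dataset(seed)
    m <- new_dta_model(small_config(use_pocket = FALSE), seed = seed)
    train_dta(m, ds[1:160, ], epochs = 120L, batch_size = 16L, lr = 1e-3,
              weight_decay = 1e-4, seed = seed)
  })
}
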