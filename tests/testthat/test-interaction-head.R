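test_that("cross-attention map is the plain matrix product P S^T", {
  # 1-D outer-product example
  alpha <- cross_attention_map(matrix(c(1, 2), 2, 1), matrix(c(3, 4), 2, 1))
  expect_equal(alpha, matrix(c(3, 6, 4, 8), 2, 2))
  # annihilation
  expect_equal(cross_attention_map(matrix(rnorm(6), 2, 3), matrix(0, 4, 3)),
               matrix(0, 2, 4))
  expect_error(cross_attention_map(matrix(0, 2, 3), matrix(0, 2, 4)),
               "widths differ")
  # brute-force triple-loop oracle
  set.seed(1)
  P <- matrix(rnorm(4 * 3), 4, 3)
  S <- matrix(rnorm(5 * 3), 5, 3)
  ref <- matrix(0, 4, 5)
  for (i in 1:4) for (j in 1:5) for (e in 1:3) {
    ref[i, j] <- ref[i, j] + P[i, e] * S[j, e]
  }
  expect_equal(cross_attention_map(P, S), ref, tolerance = 1e-12)
})

test_that("cross-attention map is bilinear in the protein features", {
  set.seed(2)
  P <- matrix(rnorm(12), 4, 3)
  S <- matrix(rnorm(9), 3, 3)
  expect_equal(cross_attention_map(2.5 * P, S),
               2.5 * cross_attention_map(P, S), tolerance = 1e-12)
})

test_that("pooling takes row means over the ligand axis", {
  alpha <- matrix(c(3, 6, 4, 8), 2, 2)
  expect_equal(pool_interaction(alpha), c(3.5, 7.0))
  expect_equal(pool_interaction(matrix(2.5, 3, 4)), rep(2.5, 3))
  # invariant to permuting ligand positions
  set.seed(3)
  a <- matrix(rnorm(5 * 7), 5, 7)
  expect_equal(pool_interaction(a[, sample(7)]), pool_interaction(a))
  # padding columns excluded when a validity mask is given
  valid <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(pool_interaction(alpha2 <- cbind(alpha, 99, 99),
                                valid = valid), c(3.5, 7.0))
})

test_that("prelu follows max(0,x) + alpha*min(0,x)", {
  expect_equal(prelu(2, 0.9), 2)
  expect_equal(prelu(-1, 0.25), -0.25)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(prelu(x, 0), pmax(x, 0))          # alpha = 0 is ReLU
  expect_equal(prelu(x, 1), x)                   # alpha = 1 is identity
})

test_that("regression head matches a hand-computed affine+PReLU chain", {
  # 2-unit toy head: beta (2) -> hidden (2, PReLU alpha .5) -> scalar
  fc <- list(list(W = matrix(c(1, 0, -1, 2), 2, 2), b = c(0.5, -1),
                  alpha = 0.5),
             list(W = matrix(c(2, -3), 2, 1), b = 0.25))
  beta <- c(1, -2)
  a1 <- c(1 * 1 + (-2) * 0 + 0.5, 1 * (-1) + (-2) * 2 - 1)  # c(1.5, -6)
  h1 <- c(1.5, 0.5 * -6)
  expected <- 2 * h1[1] + (-3) * h1[2] + 0.25
  expect_equal(regress(beta, fc, mode = "eval"), expected, tolerance = 1e-9)
})

test_that("eval mode is deterministic; train mode dropout perturbs", {
  cfg <- small_config()
  m <- new_dta_model(cfg, seed = 11)
  fc <- seqdta:::branch_fc(m$params, seqdta:::make_name_table(cfg))
  set.seed(1)
  beta <- rnorm(cfg$fc_widths[1])
  expect_identical(regress(beta, fc, "eval"), regress(beta, fc, "eval"))
  set.seed(2)
  r1 <- regress(beta, fc, "train", dropout_p = 0.5)
  r2 <- regress(beta, fc, "train", dropout_p = 0.5)
  expect_false(isTRUE(all.equal(r1, r2)))
  expect_error(regress(beta[-1], fc, "eval"), "does not match")
})

test_that("zero weights reduce the head to its final bias", {
  fc <- list(list(W = matrix(0, 3, 2), b = c(0, 0), alpha = 0.25),
             list(W = matrix(0, 2, 1), b = 4.25))
  expect_equal(regress(c(1, 2, 3), fc, "eval"), 4.25)
})

test_that("model output is a finite scalar for any valid input pair", {
  cfg <- small_config()
  m <- new_dta_model(cfg, seed = 13)
  set.seed(14)
  for (i in 1:5) {
    np <- sample(1:cfg$protein_length, 1)
    ns <- sample(1:cfg$smiles_length, 1)
    s <- list(p_idx = c(sample(1:20, np, TRUE),
                        rep(0L, cfg$protein_length - np)),
              k_idx = NULL,
              s_idx = c(sample(1:52, ns, TRUE),
                        rep(0L, cfg$smiles_length - ns)))
    y <- seqdta:::model_forward(m, s)$y
    expect_length(y, 1L)
    expect_true(is.finite(y))
  }
})

test_that("zero-pocket fusion reproduces the pocket-free (v2) forward pass", {
  cfg1 <- small_config(dropout_p = 0)
  cfg2 <- small_config(use_pocket = FALSE, dropout_p = 0)
  m1 <- new_dta_model(cfg1, seed = 21)
  m2 <- new_dta_model(cfg2, seed = 21)  # same seed -> identical weights
  expect_identical(names(m1$params), names(m2$params))
  set.seed(22)
  s <- list(p_idx = c(sample(1:20, 30, TRUE), rep(0L, 18)),
            k_idx = rep(0L, 48),  # pocket present but all-zero
            s_idx = c(sample(1:52, 10, TRUE), rep(0L, 14)))
  y1 <- seqdta:::model_forward(m1, s)$y
  y2 <- seqdta:::model_forward(m2, list(p_idx = s$p_idx, k_idx = NULL,
                                        s_idx = s$s_idx))$y
  expect_equal(y1, y2, tolerance = 1e-12)
})

test_that("concat-head variant feeds a 2E-wide head", {
  cfg <- small_config(interaction = "concat")
  expect_identical(cfg$fc_widths[1], 2L * cfg$embed_dim)
  m <- new_dta_model(cfg, seed = 23)
  set.seed(24)
  s <- list(p_idx = c(sample(1:20, 20, TRUE), rep(0L, 28)), k_idx = NULL,
            s_idx = c(sample(1:52, 10, TRUE), rep(0L, 14)))
  expect_true(is.finite(seqdta:::model_forward(m, s)$y))
})
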