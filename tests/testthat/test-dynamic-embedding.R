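make_filters <- function(kernel_sizes, filter_counts, E, seed = 1) {
  set.seed(seed)
  lapply(seq_along(kernel_sizes), function(j) {
    k <- kernel_sizes[j]
    list(W = matrix(rnorm(k * E * filter_counts[j], sd = 0.2),
                    k * E, filter_counts[j]),
         b = rnorm(filter_counts[j], sd = 0.1))
  })
}

test_that("padding index embeds to the zero vector; lookups are deterministic", {
  cfg <- small_config()
  m <- new_dta_model(cfg, seed = 3)
  emb <- m$params[["p.emb"]]
  expect_equal(embed_tokens(rep(0L, 5), emb), matrix(0, 5, cfg$embed_dim))
  idx <- c(3L, 0L, 7L, 7L, 0L)
  expect_identical(embed_tokens(idx, emb), embed_tokens(idx, emb))
  expect_equal(embed_tokens(idx, emb)[3, ], embed_tokens(idx, emb)[4, ])
  expect_error(embed_tokens(c(0L, 99L), emb), "out of range")
})

test_that("full-scale embedding and convolution shapes match the architecture", {
  # E = 128 in, H = 32+32+64+128 = 256 out, length preserved at 1024
  E <- 128L
  filters <- make_filters(c(1L, 3L, 5L, 7L), c(32L, 32L, 64L, 128L), E)
  X <- matrix(rnorm(1024 * E, sd = 0.1), 1024, E)
  H <- multiscale_conv(X, filters, c(1L, 3L, 5L, 7L))
  expect_identical(dim(H), c(1024L, 256L))
})

test_that("concatenated channel blocks equal standalone single-kernel convolutions", {
  E <- 6L
  ks <- c(1L, 3L, 5L)
  fc <- c(2L, 3L, 4L)
  filters <- make_filters(ks, fc, E, seed = 5)
  X <- matrix(rnorm(20 * E), 20, E)
  H <- multiscale_conv(X, filters, ks)
  off <- 0L
  for (j in seq_along(ks)) {
    alone <- multiscale_conv(X, filters[j], ks[j])
    expect_equal(H[, off + seq_len(fc[j])], alone, tolerance = 1e-12)
    off <- off + fc[j]
  }
})

test_that("convolution receptive fields are exactly the kernel widths", {
  E <- 4L
  filters <- make_filters(c(7L), c(3L), E, seed = 9)
  set.seed(11)
  X <- matrix(rnorm(30 * E), 30, E)
  H0 <- multiscale_conv(X, filters, 7L)
  X2 <- X
  j <- 15L
  X2[j, ] <- X2[j, ] + rnorm(E)
  H1 <- multiscale_conv(X2, filters, 7L)
  changed <- which(rowSums(abs(H1 - H0)) > 1e-12)
  expect_true(all(abs(changed - j) <= 3))

  # kernel size 1: position i depends on row i alone
  f1 <- make_filters(c(1L), c(2L), E, seed = 10)
  Xz <- matrix(0, 30, E)
  Xz[j, ] <- X[j, ]
  expect_equal(multiscale_conv(X, f1, 1L)[j, ],
               multiscale_conv(Xz, f1, 1L)[j, ], tolerance = 1e-12)
})

test_that("highway gate interpolates between identity and transform", {
  H <- 5L
  set.seed(2)
  ft <- matrix(rnorm(8 * H), 8, H)
  W <- matrix(rnorm(H * H, sd = 0.3), H, H)
  b <- rnorm(H, sd = 0.1)
  # gate forced open (bias -> +large): output is the input exactly
  expect_equal(highway(ft, W, b, Wg = matrix(0, H, H), bg = rep(50, H)),
               ft, tolerance = 1e-12)
  # gate forced shut: output is ReLU(W ft + b)
  shut <- highway(ft, W, b, Wg = matrix(0, H, H), bg = rep(-50, H))
  expect_equal(shut, pmax(sweep(ft %*% W, 2, b, `+`), 0), tolerance = 1e-12)
})

test_that("highway matches the hand-evaluated two-unit example", {
  # ft = [1, -1], W = I, b = 0, Wg = 0, bg = 0:
  # g = sigmoid(0) = 0.5; ReLU(ft) = [1, 0]; out = [1.0, -0.5]
  out <- highway(matrix(c(1, -1), 1, 2), diag(2), c(0, 0),
                 matrix(0, 2, 2), c(0, 0))
  expect_equal(as.numeric(out), c(1.0, -0.5), tolerance = 1e-12)
})

test_that("open-gate highway has identity Jacobian (finite differences)", {
  H <- 3L
  set.seed(4)
  W <- matrix(rnorm(H * H), H, H)
  Wg <- matrix(0, H, H)
  b <- rnorm(H)
  ft <- matrix(rnorm(H), 1, H)
  eps <- 1e-6
  for (i in seq_len(H)) {
    ft1 <- ft; ft1[1, i] <- ft1[1, i] + eps
    jac_col <- (highway(ft1, W, b, Wg, rep(60, H)) -
                  highway(ft, W, b, Wg, rep(60, H))) / eps
    expect_equal(as.numeric(jac_col), as.numeric(diag(H)[i, ]),
                 tolerance = 1e-4)
  }
})

test_that("projection maps hidden width to model width per position", {
  Hm <- matrix(rnorm(12 * 256), 12, 256)
  W <- matrix(rnorm(256 * 128, sd = 0.05), 256, 128)
  b <- rnorm(128)
  out <- project_to_model_dim(Hm, W, b)
  expect_identical(dim(out), c(12L, 128L))
  # zero input gives bias-only constant rows
  z <- project_to_model_dim(matrix(0, 4, 256), W, b)
  expect_equal(z, matrix(b, 4, 128, byrow = TRUE), tolerance = 1e-12)
})

test_that("end-to-end dynamic embedding yields (fixed_length, E) for any sequence", {
  cfg <- dta_config()  # full scale: L_P = 1024, E = 128
  m <- new_dta_model(cfg, seed = 1)
  enc <- encode_sequence(paste(rep("ACDEFGHIK", 20), collapse = ""),
                         protein_dictionary(), cfg$protein_length)
  out <- seqdta:::branch_embed_fwd(enc$indices, m$params,
                                   seqdta:::make_name_table(cfg)$p, cfg)$out
  expect_identical(dim(out), c(1024L, 128L))
})

test_that("an all-padding sequence maps to constant-per-position vectors", {
  cfg <- small_config()
  m <- new_dta_model(cfg, seed = 6)
  out <- seqdta:::branch_embed_fwd(rep(0L, cfg$protein_length), m$params,
                                   seqdta:::make_name_table(cfg)$p, cfg)$out
  # all rows identical: same-padded convolution of a constant zero input
  expect_lt(max(abs(sweep(out, 2L, out[1, ]))), 1e-12)
})

test_that("pocket fusion is commutative, additive, and identity at zero", {
  set.seed(3)
  a <- matrix(rnorm(40), 10, 4)
  b <- matrix(rnorm(40), 10, 4)
  expect_equal(fuse_pocket(a, matrix(0, 10, 4)), a)
  expect_equal(fuse_pocket(a, b), fuse_pocket(b, a))
  expect_error(fuse_pocket(a, matrix(0, 5, 4)), "shape")
  # pocket covering the whole protein with identical tokens doubles the
  # stream (shared embedding weights)
  cfg <- small_config()
  m <- new_dta_model(cfg, seed = 8)
  idx <- c(rep(4L, 10L), rep(0L, cfg$protein_length - 10L))
  zp <- seqdta:::branch_embed_fwd(idx, m$params,
                                  seqdta:::make_name_table(cfg)$p, cfg)$out
  expect_equal(fuse_pocket(zp, zp), 2 * zp, tolerance = 1e-12)
})
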