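#' Dynamic word-embedding layers
#'
#' The dynamic word-embedding stage maps a fixed-length integer index array
#' to one vector per sequence position whose value depends on the
#' surrounding tokens: embedding lookup, multi-kernel 1D convolution along
#' the position axis, concatenation of the kernel outputs into a hidden
#' vector, a highway gate, and a linear projection back to the model width.
#' All functions here are pure: weights are passed explicitly, so the same
#' code serves the protein, pocket (shared with protein) and ligand
#' streams. Backward-pass companions (internal) mirror each forward
#' function for training.
#'
#' @name dynamic_embedding
NULL

#' Embedding lookup
#'
#' Row `i` of the result is the embedding vector of the token at position
#' `i`. The padding index 0 always maps to the all-zero vector (row 1 of
#' the embedding matrix is held at zero and never updated), so padded tail
#' positions carry no signal.
#'
#' @param encoded an `encoded_sequence` or a bare integer index vector.
#' @param embedding numeric matrix `V x E`; row `v+1` is the vector of
#'   token index `v`.
#' @return Numeric matrix `L x E`.
#' @export
embed_tokens <- function(encoded, embedding) {
  idx <- if (inherits(encoded, "encoded_sequence")) encoded$indices else encoded
  if (any(idx >= nrow(embedding))) {
    stop("token index ", max(idx), " out of range for vocabulary of size ",
         nrow(embedding))
  }
  if (any(idx < 0)) stop("negative token index")
  embedding[idx + 1L, , drop = FALSE]
}

embed_backward <- function(idx, d_out, V) {
  d_emb <- matrix(0, V, ncol(d_out))
  nz <- idx > 0L
  if (any(nz)) {
    acc <- rowsum(d_out[nz, , drop = FALSE], group = idx[nz])
    d_emb[as.integer(rownames(acc)) + 1L, ] <- acc
  }
  d_emb  # row 1 (padding) stays zero: frozen
}

# broadcast a per-column bias over the rows of M
add_bias <- function(M, b) M + rep(b, each = nrow(M))

# position-gather index for a same-padded 1D convolution of width k (odd);
# entries are source rows, 0 marking out-of-range (zero-padded) taps
conv_positions <- function(L, k) {
  offs <- seq.int(-(k - 1L) / 2L, (k - 1L) / 2L)
  pos <- outer(seq_len(L), offs, `+`)
  pos[pos < 1L | pos > L] <- 0L
  pos
}

# im2col: L x (k*E) matrix, offset-major column blocks
conv_im2col <- function(X, pos) {
  Xpad <- rbind(0, X)
  do.call(cbind, lapply(seq_len(ncol(pos)),
                        function(m) Xpad[pos[, m] + 1L, , drop = FALSE]))
}

#' Multi-kernel 1D convolution
#'
#' Convolves the embedded sequence along the position axis once per kernel
#' size with "same" zero padding (output length equals input length) and
#' concatenates the channel blocks in kernel-size order. With the default
#' kernel sizes 1/3/5/7 and filter counts 32/32/64/128 the concatenated
#' width is the hidden size H = 256: the first block sees each position
#' alone, later blocks see progressively wider neighbourhoods.
#'
#' @param X numeric matrix `L x E` (embedded sequence).
#' @param filters list with one element per kernel: `list(W, b)` where `W`
#'   is `(k*E) x F` (taps ordered offset-major) and `b` length `F`.
#' @param kernel_sizes integer vector of odd kernel widths, parallel to
#'   `filters`.
#' @return Numeric matrix `L x H`, `H = sum of filter counts`.
#' @export
multiscale_conv <- function(X, filters, kernel_sizes) {
  stopifnot(length(filters) == length(kernel_sizes),
            all(kernel_sizes %% 2L == 1L))
  out <- multiscale_conv_fwd(X, filters, kernel_sizes)
  out$H
}

multiscale_conv_fwd <- function(X, filters, kernel_sizes) {
  L <- nrow(X)
  cols <- vector("list", length(filters))
  outs <- vector("list", length(filters))
  poss <- vector("list", length(filters))
  for (j in seq_along(filters)) {
    pos <- conv_positions(L, kernel_sizes[j])
    Xc <- conv_im2col(X, pos)
    stopifnot(ncol(Xc) == nrow(filters[[j]]$W))
    outs[[j]] <- add_bias(Xc %*% filters[[j]]$W, filters[[j]]$b)
    cols[[j]] <- Xc
    poss[[j]] <- pos
  }
  list(H = do.call(cbind, outs), cols = cols, pos = poss,
       widths = vapply(filters, function(f) ncol(f$W), integer(1)))
}

multiscale_conv_bwd <- function(cache, filters, d_H, L, E) {
  d_X <- matrix(0, L, E)
  d_filters <- vector("list", length(filters))
  off <- 0L
  for (j in seq_along(filters)) {
    Fj <- cache$widths[j]
    d_out <- d_H[, off + seq_len(Fj), drop = FALSE]
    off <- off + Fj
    d_filters[[j]] <- list(W = crossprod(cache$cols[[j]], d_out),
                           b = colSums(d_out))
    d_col <- d_out %*% t(filters[[j]]$W)
    pos <- cache$pos[[j]]
    for (m in seq_len(ncol(pos))) {
      valid <- pos[, m] > 0L
      if (any(valid)) {
        rows <- pos[valid, m]
        d_X[rows, ] <- d_X[rows, ] +
          d_col[valid, (m - 1L) * E + seq_len(E), drop = FALSE]
      }
    }
  }
  list(d_X = d_X, d_filters = d_filters)
}

#' Highway gate
#'
#' One highway layer: `x = g * f + (1 - g) * ReLU(W f + b)` with gate
#' `g = sigmoid(Wg f + bg)`, applied independently at every sequence
#' position. The sigmoid gate interpolates elementwise between passing the
#' input through unchanged (`g -> 1`) and the transformed path (`g -> 0`),
#' keeping a short gradient path through deep stacks.
#'
#' @param ft numeric matrix `L x H` (convolution output).
#' @param W,b transform weights `H x H` and bias length `H`.
#' @param Wg,bg gate weights `H x H` and bias length `H`.
#' @return Numeric matrix `L x H`.
#' @export
highway <- function(ft, W, b, Wg, bg) {
  highway_fwd(ft, list(W = W, b = b, Wg = Wg, bg = bg))$out
}

highway_fwd <- function(ft, p) {
  Apre <- add_bias(ft %*% p$W, p$b)
  Tr <- pmax(Apre, 0)
  Gpre <- add_bias(ft %*% p$Wg, p$bg)
  G <- 1 / (1 + exp(-Gpre))
  list(out = G * ft + (1 - G) * Tr, ft = ft, Apre = Apre, Tr = Tr, G = G)
}

highway_bwd <- function(cache, p, d_out) {
  d_G <- d_out * (cache$ft - cache$Tr)
  d_Tr <- d_out * (1 - cache$G)
  d_Apre <- d_Tr * (cache$Apre > 0)
  d_Gpre <- d_G * cache$G * (1 - cache$G)
  list(d_ft = d_out * cache$G + d_Apre %*% t(p$W) + d_Gpre %*% t(p$Wg),
       d_W = crossprod(cache$ft, d_Apre), d_b = colSums(d_Apre),
       d_Wg = crossprod(cache$ft, d_Gpre), d_bg = colSums(d_Gpre))
}

#' Projection to model width
#'
#' Per-position linear map from the hidden width H (concatenated
#' convolution channels) down to the model/attention width E, reconciling
#' the 256-channel convolution output with the 8 x 16 = 128-wide attention
#' stack.
#'
#' @param hidden numeric matrix `L x H`.
#' @param W projection weights `H x E`.
#' @param b bias, length `E`.
#' @return Numeric matrix `L x E`.
#' @export
project_to_model_dim <- function(hidden, W, b) {
  add_bias(hidden %*% W, b)
}

#' Position-wise pocket fusion
#'
#' Adds the dynamically embedded pocket stream onto the protein stream,
#' position by position, so attention concentrates on active-site
#' positions. A pocket stream that is all zero (no pocket information)
#' leaves the protein stream unchanged, which is exactly how the
#' pocket-free v2 variant arises from v1.
#'
#' @param protein_vectors,pocket_vectors numeric matrices of equal shape
#'   `L x E`.
#' @return Their elementwise sum.
#' @export
fuse_pocket <- function(protein_vectors, pocket_vectors) {
  if (!identical(dim(protein_vectors), dim(pocket_vectors))) {
    stop("protein and pocket streams must have identical shape")
  }
  protein_vectors + pocket_vectors
}

#' Sinusoidal positional encoding
#'
#' Standard fixed sin/cos positional encoding matrix, added to the
#' attention input only when the positional-encoding variant flag is on
#' (off by default: the convolutional embedding already carries positional
#' context, and adding explicit position codes is redundant).
#'
#' @param L sequence length.
#' @param E model width (even).
#' @return Numeric matrix `L x E`.
#' @export
positional_encoding <- function(L, E) {
  stopifnot(E %% 2L == 0L)
  pos <- seq_len(L) - 1L
  i <- seq_len(E / 2L) - 1L
  ang <- outer(pos, 1 / 10000^(2 * i / E))
  out <- matrix(0, L, E)
  out[, 2L * i + 1L] <- sin(ang)
  out[, 2L * i + 2L] <- cos(ang)
  out
}
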