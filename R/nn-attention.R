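#' Split-head self-attention
#'
#' The attention stack contextualises each position's vector by a weighted
#' mixture of every other position. Instead of projecting the full model
#' width into each head, the feature axis is split into k contiguous
#' blocks (one per head) and scaled dot-product attention runs on each
#' block independently through per-head square projection matrices without
#' bias; the head outputs are concatenated and passed through a final
#' output projection. Padded positions (token index 0) are masked out as
#' attention keys so the zero tail of a fixed-length sequence cannot
#' absorb probability mass.
#'
#' @name attention_core
NULL

#' Split the feature axis into heads
#'
#' @param X numeric matrix `L x E`.
#' @param k number of heads; must divide E.
#' @return List of k matrices `L x (E/k)` (contiguous column blocks, in
#'   order; `do.call(cbind, .)` recovers `X`).
#' @export
split_heads <- function(X, k) {
  E <- ncol(X)
  if (E %% k != 0L) stop("model width ", E, " not divisible by ", k, " heads")
  d <- E %/% k
  lapply(seq_len(k), function(i) X[, (i - 1L) * d + seq_len(d), drop = FALSE])
}

# row softmax tolerating -Inf-masked columns; fully masked rows give zeros
masked_row_softmax <- function(S) {
  n <- nrow(S)
  m <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
  m[!is.finite(m)] <- 0
  Z <- exp(S - m)
  Z[!is.finite(Z)] <- 0
  rs <- rowSums(Z)
  rs[rs == 0] <- 1
  Z / rs
}

#' Scaled dot-product attention for one head
#'
#' `softmax(Q K' / sqrt(d_k)) V`, computed row-wise. Scaling by the square
#' root of the head width keeps the logits in a range where softmax
#' gradients do not vanish. Key positions listed in `mask` as invalid
#' receive a score of `-Inf` and therefore zero attention weight.
#'
#' @param Q,K,V numeric matrices `L x d_k` with equal row counts.
#' @param mask optional logical vector of length L; `FALSE` marks padded
#'   key positions to exclude.
#' @param return_weights if `TRUE`, attach the `L x L` attention-weight
#'   matrix as attribute `"weights"`.
#' @return Numeric matrix `L x d_k`.
#' @export
head_attention <- function(Q, K, V, mask = NULL, return_weights = FALSE) {
  stopifnot(nrow(Q) == nrow(K), nrow(K) == nrow(V), ncol(Q) == ncol(K))
  d_k <- ncol(Q)
  S <- tcrossprod(Q, K) / sqrt(d_k)
  if (!is.null(mask)) S[, !mask] <- -Inf
  A <- masked_row_softmax(S)
  out <- A %*% V
  if (return_weights) attr(out, "weights") <- A
  out
}

#' Multi-head attention layer
#'
#' Splits `X` into head blocks, applies per-head Q/K/V projections (square
#' `d_k x d_k` matrices, no bias) and scaled dot-product attention,
#' concatenates the heads and applies the output projection `WO`.
#'
#' @param X numeric matrix `L x E`.
#' @param weights list: `heads` (list of k elements each holding `Wq`,
#'   `Wk`, `Wv`, all `d_k x d_k`) and `WO` (`E x E`).
#' @param mask optional logical key mask of length L.
#' @return Numeric matrix `L x E`.
#' @export
multi_head <- function(X, weights, mask = NULL) {
  attn_layer_fwd(X, weights, mask, residual = FALSE)$out
}

attn_layer_fwd <- function(X, wl, mask, residual) {
  k <- length(wl$heads)
  E <- ncol(X)
  d <- E %/% k
  L <- nrow(X)
  M <- matrix(0, L, E)
  heads <- vector("list", k)
  for (i in seq_len(k)) {
    blk <- (i - 1L) * d + seq_len(d)
    Xi <- X[, blk, drop = FALSE]
    hp <- wl$heads[[i]]
    Q <- Xi %*% hp$Wq; K <- Xi %*% hp$Wk; V <- Xi %*% hp$Wv
    S <- tcrossprod(Q, K) / sqrt(d)
    if (!is.null(mask)) S[, !mask] <- -Inf
    A <- masked_row_softmax(S)
    M[, blk] <- A %*% V
    heads[[i]] <- list(Xi = Xi, Q = Q, K = K, V = V, A = A)
  }
  O <- M %*% wl$WO
  list(out = if (residual) X + O else O, X = X, M = M, heads = heads)
}

attn_layer_bwd <- function(cache, wl, d_out, residual) {
  k <- length(wl$heads)
  E <- ncol(cache$X)
  d <- E %/% k
  d_WO <- crossprod(cache$M, d_out)
  d_M <- d_out %*% t(wl$WO)
  d_X <- if (residual) d_out else matrix(0, nrow(cache$X), E)
  d_heads <- vector("list", k)
  s <- sqrt(d)
  for (i in seq_len(k)) {
    blk <- (i - 1L) * d + seq_len(d)
    hc <- cache$heads[[i]]
    hp <- wl$heads[[i]]
    d_head <- d_M[, blk, drop = FALSE]
    d_A <- tcrossprod(d_head, hc$V)
    d_V <- crossprod(hc$A, d_head)
    d_S <- hc$A * (d_A - rowSums(d_A * hc$A))
    d_Q <- (d_S %*% hc$K) / s
    d_K <- (crossprod(d_S, hc$Q)) / s
    d_heads[[i]] <- list(Wq = crossprod(hc$Xi, d_Q),
                         Wk = crossprod(hc$Xi, d_K),
                         Wv = crossprod(hc$Xi, d_V))
    d_X[, blk] <- d_X[, blk] +
      d_Q %*% t(hp$Wq) + d_K %*% t(hp$Wk) + d_V %*% t(hp$Wv)
  }
  list(d_X = d_X, d_WO = d_WO, d_heads = d_heads)
}

#' Stacked self-attention encoder
#'
#' Applies `multi_head` `num_layers` times, with a residual connection
#' around each layer when `residual` is on (the default; the residual path
#' keeps a 6-layer stack trainable without layer normalisation). Zero
#' layers is the identity.
#'
#' @param X numeric matrix `L x E`.
#' @param layers list of per-layer weight lists (see [multi_head()]).
#' @param mask optional logical key mask of length L.
#' @param residual logical; add the layer input to its output.
#' @return Numeric matrix `L x E`.
#' @export
encode_stack <- function(X, layers, mask = NULL, residual = TRUE) {
  for (wl in layers) {
    X <- attn_layer_fwd(X, wl, mask, residual)$out
  }
  X
}

stack_fwd <- function(X, layers, mask, residual) {
  caches <- vector("list", length(layers))
  for (l in seq_along(layers)) {
    cc <- attn_layer_fwd(X, layers[[l]], mask, residual)
    caches[[l]] <- cc
    X <- cc$out
  }
  list(out = X, caches = caches)
}

stack_bwd <- function(caches, layers, d_out, residual) {
  d_layers <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    bw <- attn_layer_bwd(caches[[l]], layers[[l]], d_out, residual)
    d_layers[[l]] <- list(WO = bw$d_WO, heads = bw$d_heads)
    d_out <- bw$d_X
  }
  list(d_X = d_out, d_layers = d_layers)
}
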