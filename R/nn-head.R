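#' Protein-ligand interaction head
#'
#' The only point where the protein and ligand streams meet: the encoded
#' protein matrix is multiplied against the transposed encoded ligand
#' matrix to give a cross-attention interaction map (one score per
#' protein-position / ligand-position pair), each protein position's row
#' is average-pooled over the ligand axis into a single interaction
#' profile vector, and that vector is regressed to a scalar affinity by a
#' small fully connected stack with PReLU activations and dropout.
#'
#' @name interaction_head
NULL

#' Cross-attention interaction map
#'
#' Plain matrix product `P %*% t(S)`: entry `(i, j)` is the dot product of
#' protein position i's feature vector with ligand position j's.
#'
#' @param P numeric matrix `L_P x E` (encoded protein).
#' @param S numeric matrix `L_S x E` (encoded ligand).
#' @return Numeric matrix `L_P x L_S`.
#' @export
cross_attention_map <- function(P, S) {
  if (ncol(P) != ncol(S)) {
    stop("feature widths differ: protein ", ncol(P), ", ligand ", ncol(S))
  }
  tcrossprod(P, S)
}

#' Pool the interaction map over the ligand axis
#'
#' Adaptive average pooling to output size 1 per protein position: entry i
#' is the mean of row i of the interaction map. When `valid` marks the
#' ligand's true (non-padding) positions, the mean runs over those columns
#' only, so the padded ligand tail does not dilute the profile.
#'
#' @param alpha numeric matrix `L_P x L_S`.
#' @param valid optional logical vector of length `L_S`; `TRUE` marks real
#'   ligand positions.
#' @return Numeric vector of length `L_P`.
#' @export
pool_interaction <- function(alpha, valid = NULL) {
  if (is.null(valid)) return(rowMeans(alpha))
  stopifnot(length(valid) == ncol(alpha))
  n <- sum(valid)
  if (n == 0L) return(numeric(nrow(alpha)))
  rowSums(alpha[, valid, drop = FALSE]) / n
}

#' Parametric ReLU
#'
#' `f(x) = max(0, x) + alpha * min(0, x)`: identity for positive inputs, a
#' learnable small slope for negative ones, avoiding dead units.
#'
#' @param x numeric vector/matrix.
#' @param alpha slope for negative inputs (learnable scalar; initialised
#'   at 0.25 in the model).
#' @return Same shape as `x`.
#' @export
prelu <- function(x, alpha) {
  pmax(x, 0) + alpha * pmin(x, 0)
}

#' Fully connected regression head
#'
#' Applies the fully connected stack to a pooled interaction profile:
#' each hidden layer is affine, then (training mode only) inverted
#' dropout, then PReLU; the final layer is a plain affine map to a single
#' scalar. Evaluation mode is deterministic: dropout is disabled and, by
#' the inverted-dropout convention, activations need no rescaling.
#'
#' @param beta numeric vector, length equal to the first FC width.
#' @param fc list of layers, each `list(W, b)`, plus scalar `alpha` on
#'   hidden layers (PReLU slope).
#' @param mode `"eval"` (deterministic) or `"train"`.
#' @param dropout_p dropout probability in `[0, 1)` (train mode only).
#' @return Scalar affinity.
#' @export
regress <- function(beta, fc, mode = c("eval", "train"), dropout_p = 0.1) {
  mode <- match.arg(mode)
  fc_fwd(beta, fc, train = (mode == "train"), dropout_p = dropout_p)$y
}

fc_fwd <- function(beta, fc, train, dropout_p) {
  nl <- length(fc)
  if (length(beta) != nrow(fc[[1]]$W)) {
    stop("input length ", length(beta), " does not match first FC width ",
         nrow(fc[[1]]$W))
  }
  x <- matrix(beta, nrow = 1L)
  layers <- vector("list", nl)
  for (m in seq_len(nl)) {
    a <- x %*% fc[[m]]$W + rep(fc[[m]]$b, each = 1L)
    cache <- list(x = x, a = a)
    if (m < nl) {
      if (train && dropout_p > 0) {
        keep <- (stats::runif(length(a)) >= dropout_p) / (1 - dropout_p)
        a <- a * keep
        cache$keep <- keep
      }
      cache$a_post <- a
      x <- prelu(a, fc[[m]]$alpha)
    } else {
      x <- a
    }
    layers[[m]] <- cache
  }
  list(y = as.numeric(x), layers = layers)
}

fc_bwd <- function(cache, fc, d_y) {
  nl <- length(fc)
  d_fc <- vector("list", nl)
  d_x <- matrix(d_y, 1L, 1L)
  for (m in rev(seq_len(nl))) {
    cc <- cache$layers[[m]]
    if (m < nl) {
      ap <- cc$a_post
      d_alpha <- sum(d_x * pmin(ap, 0))
      d_a <- d_x * ifelse(ap > 0, 1, fc[[m]]$alpha)
      if (!is.null(cc$keep)) d_a <- d_a * cc$keep
    } else {
      d_alpha <- NULL
      d_a <- d_x
    }
    d_fc[[m]] <- list(W = crossprod(cc$x, d_a), b = as.numeric(d_a),
                      alpha = d_alpha)
    d_x <- d_a %*% t(fc[[m]]$W)
  }
  list(d_beta = as.numeric(d_x), d_fc = d_fc)
}
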