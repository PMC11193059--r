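#' Model configuration
#'
#' Collects every architecture hyperparameter. Defaults are the full-scale
#' settings: 128-wide embeddings, kernels 1/3/5/7 with 32/32/64/128
#' filters (hidden width 256), a single highway layer, 8 attention heads
#' of width 16 over 6 layers, protein/pocket length 1024, SMILES length
#' 256, and a 1024/256/64/1 fully connected head. Smaller settings are
#' appropriate for quick experiments and the bundled synthetic data.
#'
#' @param protein_vocab,smiles_vocab vocabulary sizes (21 and 53 for the
#'   shipped dictionaries).
#' @param embed_dim model/attention width E; must be divisible by
#'   `num_heads`.
#' @param kernel_sizes odd convolution widths, parallel to
#'   `filter_counts`; the hidden width H is `sum(filter_counts)`.
#' @param filter_counts output channels per kernel size.
#' @param highway_layers number of highway layers after the convolution.
#' @param num_heads,num_layers attention heads and stacked layers.
#' @param protein_length,smiles_length fixed encoded lengths L_P and L_S.
#' @param fc_hidden hidden widths of the regression head (the input width
#'   is `protein_length` for the cross-attention head, `2 * embed_dim` for
#'   the concatenation variant; the output width is always 1).
#' @param dropout_p dropout probability on hidden FC layers.
#' @param use_positional_encoding add sinusoidal position codes before the
#'   first attention layer (ablation variant; off by default since the
#'   convolutional embedding already encodes position context).
#' @param use_residual residual connections around each attention layer.
#' @param dynamic_embedding use the convolution/highway dynamic embedding
#'   (`FALSE` gives the static-lookup ablation variant).
#' @param interaction `"cross-attention"` (interaction map + pooling) or
#'   `"concat"` (mean-pooled streams concatenated; ablation variant).
#' @param use_pocket fuse the pocket stream into the protein stream (v1);
#'   `FALSE` is the sequence-only v2 variant.
#' @return An object of class `dta_config`.
#' @export
dta_config <- function(protein_vocab = 21L, smiles_vocab = 53L,
                       embed_dim = 128L,
                       kernel_sizes = c(1L, 3L, 5L, 7L),
                       filter_counts = c(32L, 32L, 64L, 128L),
                       highway_layers = 1L,
                       num_heads = 8L, num_layers = 6L,
                       protein_length = 1024L, smiles_length = 256L,
                       fc_hidden = c(256L, 64L),
                       dropout_p = 0.1,
                       use_positional_encoding = FALSE,
                       use_residual = TRUE,
                       dynamic_embedding = TRUE,
                       interaction = c("cross-attention", "concat"),
                       use_pocket = TRUE) {
  interaction <- match.arg(interaction)
  stopifnot(length(kernel_sizes) == length(filter_counts),
            all(kernel_sizes %% 2L == 1L),
            embed_dim %% num_heads == 0L,
            highway_layers >= 1L, num_layers >= 0L,
            protein_length >= 1L, smiles_length >= 1L,
            dropout_p >= 0, dropout_p < 1)
  hidden_dim <- sum(filter_counts)
  fc_in <- if (interaction == "cross-attention") protein_length else
    2L * embed_dim
  structure(list(
    protein_vocab = as.integer(protein_vocab),
    smiles_vocab = as.integer(smiles_vocab),
    embed_dim = as.integer(embed_dim),
    kernel_sizes = as.integer(kernel_sizes),
    filter_counts = as.integer(filter_counts),
    hidden_dim = as.integer(hidden_dim),
    highway_layers = as.integer(highway_layers),
    num_heads = as.integer(num_heads),
    head_dim = as.integer(embed_dim %/% num_heads),
    num_layers = as.integer(num_layers),
    protein_length = as.integer(protein_length),
    smiles_length = as.integer(smiles_length),
    fc_widths = as.integer(c(fc_in, fc_hidden, 1L)),
    dropout_p = dropout_p,
    use_positional_encoding = use_positional_encoding,
    use_residual = use_residual,
    dynamic_embedding = dynamic_embedding,
    interaction = interaction,
    use_pocket = use_pocket
  ), class = "dta_config")
}

#' Named model variants
#'
#' Shorthand for the model family and its ablations: `"v1"` (protein +
#' pocket + ligand), `"v2"` (no pocket), `"static-embedding"` (lookup
#' embedding instead of the dynamic convolution/highway stage),
#' `"no-self-attention"` (attention stack removed), `"concat-head"`
#' (interaction map replaced by concatenated mean-pooled streams) and
#' `"positional-encoding"` (sinusoidal codes added before attention).
#'
#' @param variant variant name.
#' @param ... further arguments to [dta_config()] (e.g. reduced sizes).
#' @return A `dta_config`.
#' @export
dta_variant <- function(variant = c("v1", "v2", "static-embedding",
                                    "no-self-attention", "concat-head",
                                    "positional-encoding"), ...) {
  variant <- match.arg(variant)
  switch(variant,
    "v1" = dta_config(...),
    "v2" = dta_config(use_pocket = FALSE, ...),
    "static-embedding" = dta_config(dynamic_embedding = FALSE, ...),
    "no-self-attention" = dta_config(num_layers = 0L, ...),
    "concat-head" = dta_config(interaction = "concat", ...),
    "positional-encoding" = dta_config(use_positional_encoding = TRUE, ...)
  )
}

#' @export
print.dta_config <- function(x, ...) {
  cat("<dta_config> E=", x$embed_dim, " H=", x$hidden_dim,
      " heads=", x$num_heads, "x", x$head_dim,
      " layers=", x$num_layers,
      " L_P=", x$protein_length, " L_S=", x$smiles_length,
      " FC=", paste(x$fc_widths, collapse = "/"),
      " [", if (x$use_pocket) "v1" else "v2",
      if (!x$dynamic_embedding) ", static-embedding",
      if (x$num_layers == 0L) ", no-self-attention",
      if (x$interaction == "concat") ", concat-head",
      if (x$use_positional_encoding) ", positional-encoding",
      "]\n", sep = "")
  invisible(x)
}

rmat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

init_branch <- function(prefix, V, cfg) {
  E <- cfg$embed_dim; H <- cfg$hidden_dim
  p <- list()
  emb <- rmat(V, E, 0.1)
  emb[1L, ] <- 0  # padding embeds to zero, frozen
  p[[paste0(prefix, ".emb")]] <- emb
  if (cfg$dynamic_embedding) {
    for (j in seq_along(cfg$kernel_sizes)) {
      k <- cfg$kernel_sizes[j]; Fo <- cfg$filter_counts[j]
      p[[paste0(prefix, ".conv", j, ".W")]] <-
        rmat(k * E, Fo, sqrt(2 / (k * E + Fo)))
      p[[paste0(prefix, ".conv", j, ".b")]] <- numeric(Fo)
    }
    for (h in seq_len(cfg$highway_layers)) {
      p[[paste0(prefix, ".hw", h, ".W")]] <- rmat(H, H, sqrt(1 / H))
      p[[paste0(prefix, ".hw", h, ".b")]] <- numeric(H)
      p[[paste0(prefix, ".hw", h, ".Wg")]] <- rmat(H, H, sqrt(1 / H))
      p[[paste0(prefix, ".hw", h, ".bg")]] <- rep(1, H)  # bias towards carry
    }
    p[[paste0(prefix, ".proj.W")]] <- rmat(H, E, sqrt(1 / H))
    p[[paste0(prefix, ".proj.b")]] <- numeric(E)
  }
  d <- cfg$head_dim
  for (l in seq_len(cfg$num_layers)) {
    for (i in seq_len(cfg$num_heads)) {
      for (w in c("Wq", "Wk", "Wv")) {
        p[[paste0(prefix, ".attn", l, ".h", i, ".", w)]] <-
          rmat(d, d, sqrt(1 / d))
      }
    }
    p[[paste0(prefix, ".attn", l, ".WO")]] <- rmat(E, E, 0.5 * sqrt(1 / E))
  }
  p
}

#' Initialise a model
#'
#' Creates a model with freshly initialised weights: small Gaussian
#' embeddings (padding row frozen at zero), Xavier-scaled convolution and
#' projection weights, highway gate bias set towards the carry path, and
#' PReLU slopes at 0.25. The protein and pocket streams share one set of
#' embedding weights; the ligand stream has its own; the two attention
#' stacks are independent.
#'
#' @param config a [dta_config()].
#' @param seed integer seed for weight initialisation.
#' @return An object of class `dta_model`: list with `config`, `params`
#'   (flat named list of weight arrays), target-standardisation constants
#'   `y_mean`/`y_sd`, and a training `manifest`.
#' @export
new_dta_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "dta_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  params <- c(init_branch("p", config$protein_vocab, config),
              init_branch("s", config$smiles_vocab, config))
  fw <- config$fc_widths
  for (m in seq_len(length(fw) - 1L)) {
    params[[paste0("fc", m, ".W")]] <-
      rmat(fw[m], fw[m + 1L], sqrt(2 / (fw[m] + fw[m + 1L])))
    params[[paste0("fc", m, ".b")]] <- numeric(fw[m + 1L])
    if (m < length(fw) - 1L) params[[paste0("fc", m, ".alpha")]] <- 0.25
  }
  structure(list(config = config, params = params,
                 names = make_name_table(config), y_mean = 0, y_sd = 1,
                 manifest = list(seed = seed, epochs_trained = 0L)),
            class = "dta_model")
}

#' @export
print.dta_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<dta_model> ", format(np, big.mark = ","), " parameters, ",
      x$manifest$epochs_trained, " epochs trained\n", sep = "")
  print(x$config)
  invisible(x)
}

# parameter-name lookup table, built once per config so the hot forward/
# backward paths never construct strings
make_name_table <- function(cfg) {
  branch <- function(prefix) {
    b <- list(emb = paste0(prefix, ".emb"))
    if (cfg$dynamic_embedding) {
      b$conv <- lapply(seq_along(cfg$kernel_sizes), function(j) {
        list(W = paste0(prefix, ".conv", j, ".W"),
             b = paste0(prefix, ".conv", j, ".b"))
      })
      b$hw <- lapply(seq_len(cfg$highway_layers), function(h) {
        list(W = paste0(prefix, ".hw", h, ".W"),
             b = paste0(prefix, ".hw", h, ".b"),
             Wg = paste0(prefix, ".hw", h, ".Wg"),
             bg = paste0(prefix, ".hw", h, ".bg"))
      })
      b$proj <- list(W = paste0(prefix, ".proj.W"),
                     b = paste0(prefix, ".proj.b"))
    }
    b$attn <- lapply(seq_len(cfg$num_layers), function(l) {
      list(WO = paste0(prefix, ".attn", l, ".WO"),
           heads = lapply(seq_len(cfg$num_heads), function(i) {
             list(Wq = paste0(prefix, ".attn", l, ".h", i, ".Wq"),
                  Wk = paste0(prefix, ".attn", l, ".h", i, ".Wk"),
                  Wv = paste0(prefix, ".attn", l, ".h", i, ".Wv"))
           }))
    })
    b
  }
  nl <- length(cfg$fc_widths) - 1L
  list(p = branch("p"), s = branch("s"),
       fc = lapply(seq_len(nl), function(m) {
         out <- list(W = paste0("fc", m, ".W"), b = paste0("fc", m, ".b"))
         if (m < nl) out$alpha <- paste0("fc", m, ".alpha")
         out
       }))
}

model_names <- function(model) {
  if (is.null(model$names)) make_name_table(model$config) else model$names
}

# gather a branch's attention weights into the nested form the attention
# layer functions expect
branch_attn_weights <- function(params, nm_branch) {
  lapply(nm_branch$attn, function(lname) {
    list(heads = lapply(lname$heads, function(hn) {
      list(Wq = params[[hn$Wq]], Wk = params[[hn$Wk]], Wv = params[[hn$Wv]])
    }),
    WO = params[[lname$WO]])
  })
}

branch_fc <- function(params, nm) {
  lapply(nm$fc, function(fn) {
    out <- list(W = params[[fn$W]], b = params[[fn$b]])
    if (!is.null(fn$alpha)) out$alpha <- params[[fn$alpha]]
    out
  })
}

# dynamic-embedding stage for one index vector; returns L x E plus cache
branch_embed_fwd <- function(idx, params, nm, cfg) {
  X <- embed_tokens(idx, params[[nm$emb]])
  cache <- list(idx = idx)
  if (!cfg$dynamic_embedding) {
    return(list(out = X, cache = cache))
  }
  filters <- lapply(nm$conv, function(cn) {
    list(W = params[[cn$W]], b = params[[cn$b]])
  })
  cv <- multiscale_conv_fwd(X, filters, cfg$kernel_sizes)
  Hm <- cv$H
  hw_caches <- vector("list", cfg$highway_layers)
  for (h in seq_len(cfg$highway_layers)) {
    hn <- nm$hw[[h]]
    hp <- list(W = params[[hn$W]], b = params[[hn$b]],
               Wg = params[[hn$Wg]], bg = params[[hn$bg]])
    hc <- highway_fwd(Hm, hp)
    hw_caches[[h]] <- hc
    Hm <- hc$out
  }
  Z <- project_to_model_dim(Hm, params[[nm$proj$W]], params[[nm$proj$b]])
  cache$X <- X; cache$conv <- cv; cache$filters <- filters
  cache$hw <- hw_caches; cache$proj_in <- Hm
  list(out = Z, cache = cache)
}

branch_embed_bwd <- function(cache, params, nm, cfg, d_Z, grads) {
  if (cfg$dynamic_embedding) {
    gadd(grads, nm$proj$W, crossprod(cache$proj_in, d_Z))
    gadd(grads, nm$proj$b, colSums(d_Z))
    d_H <- d_Z %*% t(params[[nm$proj$W]])
    for (h in rev(seq_len(cfg$highway_layers))) {
      hn <- nm$hw[[h]]
      hp <- list(W = params[[hn$W]], b = params[[hn$b]],
                 Wg = params[[hn$Wg]], bg = params[[hn$bg]])
      bw <- highway_bwd(cache$hw[[h]], hp, d_H)
      gadd(grads, hn$W, bw$d_W)
      gadd(grads, hn$b, bw$d_b)
      gadd(grads, hn$Wg, bw$d_Wg)
      gadd(grads, hn$bg, bw$d_bg)
      d_H <- bw$d_ft
    }
    cb <- multiscale_conv_bwd(cache$conv, cache$filters, d_H,
                              nrow(cache$X), cfg$embed_dim)
    for (j in seq_along(nm$conv)) {
      gadd(grads, nm$conv[[j]]$W, cb$d_filters[[j]]$W)
      gadd(grads, nm$conv[[j]]$b, cb$d_filters[[j]]$b)
    }
    d_X <- cb$d_X
  } else {
    d_X <- d_Z
  }
  gadd(grads, nm$emb, embed_backward(cache$idx, d_X, nrow(params[[nm$emb]])))
  invisible(NULL)
}

# full forward pass for one encoded sample
# sample: list(p_idx, k_idx (or NULL), s_idx)
model_forward <- function(model, sample, train = FALSE) {
  cfg <- model$config
  pr <- model$params
  nm <- model_names(model)
  pe <- branch_embed_fwd(sample$p_idx, pr, nm$p, cfg)
  Zp <- pe$out
  ke <- NULL
  if (cfg$use_pocket && !is.null(sample$k_idx) && any(sample$k_idx > 0L)) {
    ke <- branch_embed_fwd(sample$k_idx, pr, nm$p, cfg)
    Zp <- fuse_pocket(Zp, ke$out)
  }
  se <- branch_embed_fwd(sample$s_idx, pr, nm$s, cfg)
  Zs <- se$out
  if (cfg$use_positional_encoding) {
    Zp <- Zp + positional_encoding(nrow(Zp), ncol(Zp))
    Zs <- Zs + positional_encoding(nrow(Zs), ncol(Zs))
  }
  mask_p <- sample$p_idx > 0L
  mask_s <- sample$s_idx > 0L
  wp <- branch_attn_weights(pr, nm$p)
  ws <- branch_attn_weights(pr, nm$s)
  sp <- stack_fwd(Zp, wp, mask_p, cfg$use_residual)
  ss <- stack_fwd(Zs, ws, mask_s, cfg$use_residual)
  P <- sp$out; S <- ss$out

  if (cfg$interaction == "cross-attention") {
    alpha <- cross_attention_map(P, S)
    beta <- pool_interaction(alpha, valid = mask_s)
  } else {
    np <- max(sum(mask_p), 1L); ns <- max(sum(mask_s), 1L)
    mp <- colSums(P[mask_p, , drop = FALSE]) / np
    ms <- colSums(S[mask_s, , drop = FALSE]) / ns
    beta <- c(mp, ms)
  }
  fc <- branch_fc(pr, nm)
  hf <- fc_fwd(beta, fc, train = train, dropout_p = cfg$dropout_p)
  list(y = hf$y,
       cache = list(pe = pe, ke = ke, se = se, sp = sp, ss = ss,
                    P = P, S = S, mask_p = mask_p, mask_s = mask_s,
                    beta = beta, hf = hf, fc = fc, wp = wp, ws = ws))
}

gadd <- function(grads, name, value) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) value else cur + value
  invisible(NULL)
}

# backward pass for one sample; accumulates into environment `grads`
model_backward <- function(model, sample, cache, d_y, grads) {
  cfg <- model$config
  pr <- model$params
  nm <- model_names(model)
  hb <- fc_bwd(cache$hf, cache$fc, d_y)
  nl <- length(cache$fc)
  for (m in seq_len(nl)) {
    gadd(grads, nm$fc[[m]]$W, hb$d_fc[[m]]$W)
    gadd(grads, nm$fc[[m]]$b, hb$d_fc[[m]]$b)
    if (m < nl) gadd(grads, nm$fc[[m]]$alpha, hb$d_fc[[m]]$alpha)
  }
  d_beta <- hb$d_beta
  P <- cache$P; S <- cache$S
  if (cfg$interaction == "cross-attention") {
    ns <- sum(cache$mask_s)
    d_alpha <- matrix(0, nrow(P), nrow(S))
    if (ns > 0L) d_alpha[, cache$mask_s] <- d_beta / ns
    d_P <- d_alpha %*% S
    d_S <- crossprod(d_alpha, P)
  } else {
    E <- cfg$embed_dim
    np <- max(sum(cache$mask_p), 1L); ns <- max(sum(cache$mask_s), 1L)
    d_P <- matrix(0, nrow(P), E); d_S <- matrix(0, nrow(S), E)
    d_P[cache$mask_p, ] <- rep(d_beta[seq_len(E)] / np, each = sum(cache$mask_p))
    d_S[cache$mask_s, ] <- rep(d_beta[E + seq_len(E)] / ns,
                               each = sum(cache$mask_s))
  }
  bp <- stack_bwd(cache$sp$caches, cache$wp, d_P, cfg$use_residual)
  bs <- stack_bwd(cache$ss$caches, cache$ws, d_S, cfg$use_residual)
  for (l in seq_len(cfg$num_layers)) {
    for (br in list(list(nm$p, bp), list(nm$s, bs))) {
      bnm <- br[[1]]; bb <- br[[2]]
      gadd(grads, bnm$attn[[l]]$WO, bb$d_layers[[l]]$WO)
      for (i in seq_len(cfg$num_heads)) {
        hh <- bb$d_layers[[l]]$heads[[i]]
        hn <- bnm$attn[[l]]$heads[[i]]
        gadd(grads, hn$Wq, hh$Wq)
        gadd(grads, hn$Wk, hh$Wk)
        gadd(grads, hn$Wv, hh$Wv)
      }
    }
  }
  d_Zp <- bp$d_X
  d_Zs <- bs$d_X
  # positional encoding is an additive constant: gradient passes through
  branch_embed_bwd(cache$se$cache, pr, nm$s, cfg, d_Zs, grads)
  branch_embed_bwd(cache$pe$cache, pr, nm$p, cfg, d_Zp, grads)
  if (!is.null(cache$ke)) {
    branch_embed_bwd(cache$ke$cache, pr, nm$p, cfg, d_Zp, grads)
  }
  invisible(NULL)
}

#' Predict affinities
#'
#' Deterministic (evaluation-mode) prediction for encoded samples or a
#' dataset table. Predictions are de-standardised back to the -log
#' affinity scale using the constants stored at training time.
#'
#' @param object a trained `dta_model`.
#' @param newdata a data frame with columns `protein_seq`, `smiles` and
#'   optionally `pocket_positions` (see [read_dataset_table()]), or a list
#'   of pre-encoded samples from [encode_records()].
#' @param ... unused.
#' @return Numeric vector of predicted affinities.
#' @export
predict.dta_model <- function(object, newdata, ...) {
  samples <- if (is.data.frame(newdata)) {
    encode_records(newdata, object$config)
  } else {
    newdata
  }
  vapply(samples, function(s) {
    object$y_mean + object$y_sd * model_forward(object, s, train = FALSE)$y
  }, numeric(1))
}

#' Encode a dataset table into model-ready samples
#'
#' Applies the shipped dictionaries to every record: the protein sequence
#' and (if present) the pocket mask are encoded to `protein_length`
#' indices, the SMILES string to `smiles_length` indices.
#'
#' @param records data frame with columns `protein_seq`, `smiles`,
#'   optionally `pocket_positions` (semicolon-separated 1-based positions)
#'   and `affinity`.
#' @param config a `dta_config` (for the fixed lengths).
#' @param protein_dict,smiles_dict token dictionaries.
#' @return List of samples: each `list(p_idx, k_idx, s_idx, y)`.
#' @export
encode_records <- function(records, config,
                           protein_dict = protein_dictionary(),
                           smiles_dict = smiles_dictionary()) {
  lapply(seq_len(nrow(records)), function(i) {
    p <- encode_sequence(records$protein_seq[i], protein_dict,
                         config$protein_length)
    s <- encode_sequence(records$smiles[i], smiles_dict,
                         config$smiles_length)
    k_idx <- NULL
    if (!is.null(records$pocket_positions) &&
        !is.na(records$pocket_positions[i]) &&
        nzchar(records$pocket_positions[i])) {
      posn <- as.integer(strsplit(records$pocket_positions[i], ";",
                                  fixed = TRUE)[[1]])
      k_idx <- integer(config$protein_length)
      posn <- posn[posn >= 1L & posn <= config$protein_length]
      k_idx[posn] <- p$indices[posn]
    }
    list(p_idx = p$indices, k_idx = k_idx, s_idx = s$indices,
         y = if (!is.null(records$affinity)) records$affinity[i] else NA_real_)
  })
}
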