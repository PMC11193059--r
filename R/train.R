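#' AdamW update for one parameter
#'
#' One step of AdamW with decoupled weight decay. The exponential moving
#' averages of the gradient (first moment `v`) and its square (second
#' moment `s`) are updated, bias-corrected by `1 - beta1^t` and
#' `1 - beta2^t`, and the parameter moves by
#' `eta * (alpha * vhat / (sqrt(shat) + eps) + lambda * x)`: the weight
#' decay multiplies the parameter directly rather than entering the
#' gradient, so the adaptive denominator cannot wash it out.
#'
#' @param param numeric scalar/vector/matrix parameter value.
#' @param gradient gradient of the loss w.r.t. `param`, same shape.
#' @param state optimizer state for this parameter: `list(t, v, s)`; pass
#'   `NULL` to start from `t = 0`, `v = s = 0`.
#' @param alpha base learning rate (default 1e-4).
#' @param beta1,beta2 moment decay rates (defaults 0.9, 0.999).
#' @param eps numerical floor in the denominator.
#' @param lambda decoupled weight-decay coefficient.
#' @param eta schedule multiplier (constant 1 by default).
#' @return `list(param, state)` with the updated value and state.
#' @export
adamw_step <- function(param, gradient, state = NULL, alpha = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       lambda = 0, eta = 1) {
  if (is.null(state)) {
    state <- list(t = 0L, v = param * 0, s = param * 0)
  }
  t <- state$t + 1L
  v <- beta1 * state$v + (1 - beta1) * gradient
  s <- beta2 * state$s + (1 - beta2) * gradient^2
  vhat <- v / (1 - beta1^t)
  shat <- s / (1 - beta2^t)
  param <- param - eta * (alpha * vhat / (sqrt(shat) + eps) + lambda * param)
  list(param = param, state = list(t = t, v = v, s = s))
}

# optimizer over a flat named parameter list; state holds parallel v/s lists
adamw_init <- function(params) {
  list(t = 0L,
       v = lapply(params, function(p) p * 0),
       s = lapply(params, function(p) p * 0))
}

adamw_update_all <- function(params, grads, state, alpha, beta1 = 0.9,
                             beta2 = 0.999, eps = 1e-8, lambda = 0.01,
                             eta = 1, decay_exempt = character(0)) {
  t <- state$t + 1L
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    v <- beta1 * state$v[[nm]] + (1 - beta1) * g
    s <- beta2 * state$s[[nm]] + (1 - beta2) * g^2
    lam <- if (nm %in% decay_exempt) 0 else lambda
    params[[nm]] <- params[[nm]] -
      eta * (alpha * (v / bc1) / (sqrt(s / bc2) + eps) + lam * params[[nm]])
    state$v[[nm]] <- v
    state$s[[nm]] <- s
  }
  state$t <- t
  list(params = params, state = state)
}

#' Mean squared error training loss
#'
#' @param predictions,targets numeric vectors of equal length.
#' @return Scalar mean of squared residuals.
#' @export
mse_loss <- function(predictions, targets) {
  stopifnot(length(predictions) == length(targets), length(targets) > 0L)
  mean((predictions - targets)^2)
}

#' Early-stopping rule
#'
#' Training stops when the epoch count reaches `max_epochs`, or when the
#' training loss has not decreased for three consecutive epochs (all three
#' epoch-over-epoch changes are >= 0) while sitting below the current
#' validation loss — the signature of a model that has stopped improving
#' without yet overfitting badly.
#'
#' @param train_losses numeric vector of per-epoch training losses so far.
#' @param val_losses matching validation losses (`NULL` disables the
#'   plateau rule, leaving only the epoch cap).
#' @param max_epochs epoch cap (default 50).
#' @return `TRUE` if training should stop now.
#' @export
should_stop <- function(train_losses, val_losses = NULL, max_epochs = 50L) {
  n <- length(train_losses)
  if (n >= max_epochs) return(TRUE)
  if (!is.null(val_losses) && n >= 4L) {
    deltas <- diff(utils::tail(train_losses, 4L))
    if (all(deltas >= 0) &&
        utils::tail(train_losses, 1L) < utils::tail(val_losses, 1L)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Balanced k-fold plan
#'
#' Seeded shuffle followed by round-robin assignment: folds are disjoint,
#' cover all indices, and differ in size by at most one.
#'
#' @param n dataset size.
#' @param k number of folds (default 10).
#' @param seed shuffle seed.
#' @return An object of class `fold_plan`: `list(k, folds, seed)` where
#'   `folds` is a list of index vectors.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  stopifnot(n >= k, k >= 2L)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  shuffled <- sample.int(n)
  folds <- lapply(seq_len(k), function(i) sort(shuffled[seq(i, n, by = k)]))
  structure(list(k = as.integer(k), folds = folds, seed = seed),
            class = "fold_plan")
}

#' Train a model
#'
#' Mini-batch AdamW training with mean-squared-error loss on standardised
#' targets (the target mean and standard deviation are estimated from the
#' training records, stored on the model, and folded back in at
#' prediction time). Optionally monitors a validation set and applies the
#' early-stopping rule.
#'
#' @param model a `dta_model` from [new_dta_model()].
#' @param records data frame of training records (see
#'   [read_dataset_table()]) or pre-encoded samples from
#'   [encode_records()] (which must then carry `y`).
#' @param epochs epoch cap (default 50).
#' @param batch_size records per optimizer step.
#' @param lr base learning rate `alpha`.
#' @param weight_decay decoupled decay `lambda`.
#' @param val_records optional validation records (same forms).
#' @param early_stop apply [should_stop()] each epoch (needs
#'   `val_records`).
#' @param seed seed for batch shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return The trained model; `model$history` holds per-epoch train (and
#'   validation) losses, `model$manifest` the run settings.
#' @export
train_dta <- function(model, records, epochs = 50L, batch_size = 32L,
                      lr = 1e-4, weight_decay = 0.01, val_records = NULL,
                      early_stop = !is.null(val_records), seed = 1L,
                      verbose = FALSE) {
  cfg <- model$config
  samples <- if (is.data.frame(records)) encode_records(records, cfg) else
    records
  y <- vapply(samples, `[[`, numeric(1), "y")
  stopifnot(!anyNA(y))
  model$y_mean <- mean(y)
  model$y_sd <- if (stats::sd(y) > 0) stats::sd(y) else 1
  y_std <- (y - model$y_mean) / model$y_sd
  vsamples <- NULL
  vy_std <- NULL
  if (!is.null(val_records)) {
    vsamples <- if (is.data.frame(val_records)) {
      encode_records(val_records, cfg)
    } else {
      val_records
    }
    vy <- vapply(vsamples, `[[`, numeric(1), "y")
    vy_std <- (vy - model$y_mean) / model$y_sd
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  state <- adamw_init(model$params)
  exempt <- grep("\\.(b|bg|alpha)$|\\.emb$", names(model$params),
                 value = TRUE)
  n <- length(samples)
  train_hist <- numeric(0)
  val_hist <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch_size)) {
      bidx <- ord[start:min(start + batch_size - 1L, n)]
      grads <- new.env(parent = emptyenv())
      bloss <- 0
      for (i in bidx) {
        fw <- model_forward(model, samples[[i]], train = TRUE)
        resid <- fw$y - y_std[i]
        bloss <- bloss + resid^2
        model_backward(model, samples[[i]], fw$cache,
                       d_y = 2 * resid / length(bidx), grads)
      }
      glist <- as.list(grads)
      upd <- adamw_update_all(model$params, glist, state, alpha = lr,
                              lambda = weight_decay, decay_exempt = exempt)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bloss / length(bidx)
      nb <- nb + 1L
    }
    train_hist <- c(train_hist, ep_loss / nb)
    if (!is.null(vsamples)) {
      vp <- vapply(vsamples, function(s) {
        model_forward(model, s, train = FALSE)$y
      }, numeric(1))
      val_hist <- c(val_hist, mse_loss(vp, vy_std))
    }
    if (verbose) {
      cat(sprintf("epoch %3d  train %.4f%s\n", ep, utils::tail(train_hist, 1),
                  if (length(val_hist)) {
                    sprintf("  val %.4f", utils::tail(val_hist, 1))
                  } else ""))
    }
    if (early_stop && should_stop(train_hist, val_hist, max_epochs = epochs)) {
      break
    }
  }
  model$history <- list(train = train_hist,
                        val = if (length(val_hist)) val_hist else NULL)
  model$manifest <- utils::modifyList(model$manifest, list(
    epochs_trained = length(train_hist), batch_size = batch_size,
    lr = lr, weight_decay = weight_decay, train_seed = seed))
  model
}

#' k-fold cross-validation
#'
#' Trains one model per fold (on the other k-1 folds) and evaluates it on
#' the held-out fold, mirroring the protocol that yields an ensemble of k
#' models whose averaged prediction is the final output.
#'
#' @param records training data frame.
#' @param config a `dta_config`.
#' @param k number of folds.
#' @param seed seed controlling fold assignment, weight init and training.
#' @param ... further arguments to [train_dta()].
#' @return List with `models` (length k), `fold_plan`, and `reports` (one
#'   `metric_report` per fold, computed on that fold's held-out records).
#' @export
crossval_dta <- function(records, config, k = 10L, seed = 1L, ...) {
  plan <- make_folds(nrow(records), k = k, seed = seed)
  models <- vector("list", k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    hold <- plan$folds[[f]]
    m <- new_dta_model(config, seed = seed + f)
    m <- train_dta(m, records[-hold, , drop = FALSE],
                   val_records = records[hold, , drop = FALSE],
                   seed = seed + f, ...)
    yhat <- predict(m, records[hold, , drop = FALSE])
    m$manifest$fold <- f
    m$manifest$validation_ids <- records$complex_id[hold]
    models[[f]] <- m
    reports[[f]] <- metric_report(records$affinity[hold], yhat)
  }
  list(models = models, fold_plan = plan, reports = reports)
}

#' Ensemble-averaged prediction
#'
#' @param models list of trained `dta_model` objects.
#' @param newdata records data frame or encoded samples.
#' @return Numeric vector: the arithmetic mean of the member predictions.
#' @export
ensemble_predict <- function(models, newdata) {
  stopifnot(length(models) >= 1L)
  preds <- vapply(models, function(m) predict(m, newdata),
                  numeric(if (is.data.frame(newdata)) nrow(newdata) else
                    length(newdata)))
  if (is.null(dim(preds))) return(mean(preds))
  rowMeans(preds)
}
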