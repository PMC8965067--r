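#' Training configuration
#'
#' Optimization settings for [train()]. The original GLTM formulation specifies the
#' objective but not the optimizer; defaults are adaptive-moment gradient
#' descent (Adam) at rate 1e-3 for 100 epochs with minibatches of 32.
#'
#' @param epochs Number of passes over the (oversampled) view list.
#' @param lr Learning rate.
#' @param batch_size Minibatch size; gradients are averaged within a batch.
#' @param oversample If `TRUE`, the minority class contributes proportionally
#'   more fresh random views per epoch so classes are balanced — the
#'   re-segmentation data-enhancement answer to class imbalance.
#' @param weight_decay Decoupled L2 regularization rate (AdamW style);
#'   counteracts memorization of individual training fragments.
#' @param seed Optional integer seed for the whole run (shuffling and window
#'   resampling), making training fully reproducible.
#' @param verbose Print a structured log line per epoch.
#' @return An object of class `gltm_train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 1e-3, batch_size = 32L,
                         oversample = TRUE, weight_decay = 0,
                         seed = NULL, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 oversample = isTRUE(oversample),
                 weight_decay = weight_decay, seed = seed,
                 verbose = isTRUE(verbose)),
            class = "gltm_train_config")
}

adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

epoch_view_ids <- function(labels, oversample) {
  ids <- seq_along(labels)
  if (!oversample) return(sample(ids))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0 || n1 == n0) return(sample(ids))
  minority <- if (n1 < n0) which(labels == 1) else which(labels == 0)
  deficit <- abs(n0 - n1)
  extra <- sample(minority, deficit, replace = TRUE)
  sample(c(ids, extra))
}

#' Train the model
#'
#' Gradient-based minimization of the penalized squared-error objective. Every
#' epoch re-segments every fragment with fresh random windows, so the model
#' sees a different encoded view of each fragment each time; annotated
#' fragments contribute the position penalty, all others the self-focus
#' penalty. Aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param fragments Fragment data frame with labels `"dimer"`/`"non-dimer"`
#'   (fragments labelled `"unknown"` are rejected).
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param validation Optional labelled fragment data frame; single-view
#'   accuracy on it is recorded per epoch.
#' @param keep_best If `TRUE` (and `validation` is given), the returned
#'   parameters are those of the epoch with the highest validation accuracy
#'   rather than the last epoch — early stopping in its simplest form.
#' @return A `gltm_model`: list with `params`, `config`, `history`
#'   (per-epoch `loss`, and `val_accuracy` if validation was given).
#' @export
train <- function(fragments, config = model_config(), tc = train_config(),
                  validation = NULL, keep_best = FALSE) {
  frags <- as_fragment_frame(fragments)
  if (nrow(frags) == 0L) stop("no fragments to train on")
  if (any(frags$label == "unknown"))
    stop("training requires known labels; found ",
         sum(frags$label == "unknown"), " fragment(s) labelled 'unknown'")
  labels <- ifelse(frags$label == "dimer", 1, 0)
  L <- nchar(frags$sequence)
  if (config$n - 1L > min(L) - config$k)
    stop("infeasible (n, k, L): need L - k >= n - 1 for every fragment")

  src <- view_source(frags)
  with_seed(tc$seed, {
    params <- init_params(config)
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    history <- list(loss = numeric(0), val_accuracy = numeric(0))
    cfg_hash <- substr(rlang_hashless_digest(config), 1, 8)
    step <- 0L
    best_acc <- NULL; best_params <- NULL; best_epoch <- NA_integer_
    for (epoch in seq_len(tc$epochs)) {
      ids <- epoch_view_ids(labels, tc$oversample)
      total <- 0
      for (b0 in seq(1L, length(ids), by = tc$batch_size)) {
        batch_ids <- ids[b0:min(b0 + tc$batch_size - 1L, length(ids))]
        views <- lapply(batch_ids, function(i)
          fast_view(src$codes[[i]], config$n, config$k, src$center[i],
                    labels[i]))
        res <- cpp_batch_loss_grad(views, config$k, config$n, params,
                                   config$sweep == "state_first",
                                   config$alpha)
        if (!is.finite(res$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (step ", step + 1L, "); lower the learning rate")
        total <- total + res$loss
        grads <- lapply(res$grads, function(g) g / length(batch_ids))
        step <- step + 1L
        upd <- adam_step(params, grads, state, tc$lr, step, tc$weight_decay)
        params <- upd$params
        state <- upd$state
      }
      history$loss <- c(history$loss, total / length(ids))
      if (!is.null(validation)) {
        acc <- quick_accuracy(validation, params, config)
        history$val_accuracy <- c(history$val_accuracy, acc)
        if (keep_best && (is.null(best_acc) || acc > best_acc)) {
          best_acc <- acc
          best_params <- params
          best_epoch <- epoch
        }
      }
      if (tc$verbose)
        message(sprintf(
          "gltm train | config=%s seed=%s epoch=%d loss=%.6f%s",
          cfg_hash, format(tc$seed), epoch, utils::tail(history$loss, 1),
          if (!is.null(validation))
            sprintf(" val_acc=%.4f", utils::tail(history$val_accuracy, 1))
          else ""))
    }
    if (keep_best && !is.null(best_params)) {
      params <- best_params
      history$best_epoch <- best_epoch
    }
    structure(list(params = params, config = config, history = history,
                   trained = TRUE),
              class = "gltm_model")
  })
}

# cheap deterministic config fingerprint for log lines (no digest dependency)
rlang_hashless_digest <- function(x) {
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

quick_accuracy <- function(frags, params, config, nviews = 3L) {
  frags <- as_fragment_frame(frags)
  src <- view_source(frags)
  ids <- rep(seq_len(nrow(frags)), each = nviews)
  views <- lapply(ids, function(i)
    fast_view(src$codes[[i]], config$n, config$k, NA_real_, src$y[i]))
  p <- cpp_batch_forward(views, config$k, config$n, params,
                         config$sweep == "state_first")$probs
  # mean probability over the views of each fragment, then threshold
  pbar <- tapply(p, ids, mean)
  mean((pbar > 0.5) == (src$y == 1))
}

#' Predict dimerization probabilities for fragments
#'
#' Runs one or more fresh stochastic views per fragment and returns the mean
#' probability and the majority-vote label.
#'
#' @param model A trained `gltm_model`.
#' @param fragments Fragment data frame.
#' @param runs Number of stochastic views per fragment.
#' @return Data frame with `id`, `prob` (mean over runs), `dimer_calls`
#'   (runs voting dimer) and `predicted_label`.
#' @export
predict_fragments <- function(model, fragments, runs = 1L) {
  stopifnot(inherits(model, "gltm_model"))
  if (!isTRUE(model$trained)) stop("model is untrained")
  frags <- as_fragment_frame(fragments)
  config <- model$config
  src <- view_source(frags)
  out <- lapply(seq_len(nrow(frags)), function(i) {
    views <- lapply(seq_len(runs), function(r)
      fast_view(src$codes[[i]], config$n, config$k, NA_real_, NA_real_))
    probs <- cpp_batch_forward(views, config$k, config$n, model$params,
                               config$sweep == "state_first")$probs
    calls <- sum(probs > 0.5)
    data.frame(id = frags$id[i], prob = mean(probs), dimer_calls = calls,
               predicted_label = if (calls > runs / 2) "dimer" else "non-dimer")
  })
  do.call(rbind, out)
}
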