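#' Model configuration
#'
#' Hyperparameters of the global-local attention network.
#'
#' @param k Window length in residues (benchmarked grid: 5, 6, 7).
#' @param n Window count per fragment view (benchmarked grid: 9-12).
#' @param u Recurrent hidden units per direction (window summaries and global
#'   states have length `2u`).
#' @param d_a Attention hidden size.
#' @param alpha Penalty weight in the training objective (>= 0).
#' @param c Constant of the window position score (cancels; kept for
#'   fidelity).
#' @param sweep Order in which the local layer consumes a window's rows:
#'   `"state_first"` feeds the overlap-state row before the residue rows in
#'   each direction, so repeated-residue information is accepted first;
#'   `"natural"` reads rows top to bottom.
#' @param seed Optional integer seed used by [init_params()].
#' @return An object of class `gltm_config`.
#' @export
model_config <- function(k = 5L, n = 12L, u = 32L, d_a = 16L, alpha = 0.1,
                         c = 0, sweep = c("state_first", "natural"),
                         seed = NULL) {
  sweep <- match.arg(sweep)
  k <- as.integer(k); n <- as.integer(n)
  u <- as.integer(u); d_a <- as.integer(d_a)
  if (any(c(k, n, u, d_a) < 1L)) stop("k, n, u, d_a must be positive")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(k = k, n = n, u = u, d_a = d_a, alpha = alpha, c = c,
                 sweep = sweep, seed = seed),
            class = "gltm_config")
}

#' @export
print.gltm_config <- function(x, ...) {
  cat(sprintf(
    "<gltm_config> k=%d n=%d u=%d d_a=%d alpha=%g c=%g sweep=%s\n",
    x$k, x$n, x$u, x$d_a, x$alpha, x$c, x$sweep))
  invisible(x)
}

glorot <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

lstm_init <- function(input, u) {
  b <- rep(0, 4 * u)
  b[(u + 1):(2 * u)] <- 1  # forget-gate bias at 1, standard LSTM practice
  list(W = glorot(4 * u, input), U = glorot(4 * u, u), b = b)
}

#' Initialize model parameters
#'
#' Glorot-scaled normal weights, zero biases except the LSTM forget gates
#' (set to 1). Deterministic under `config$seed`.
#'
#' @param config A [model_config()].
#' @return A named list of parameter matrices/vectors.
#' @export
init_params <- function(config) {
  stopifnot(inherits(config, "gltm_config"))
  u <- config$u
  with_seed(config$seed, {
    lf <- lstm_init(22L, u); lb <- lstm_init(22L, u)
    gf <- lstm_init(2L * u, u); gb <- lstm_init(2L * u, u)
    list(Wlf = lf$W, Ulf = lf$U, blf = lf$b,
         Wlb = lb$W, Ulb = lb$U, blb = lb$b,
         Wgf = gf$W, Ugf = gf$U, bgf = gf$b,
         Wgb = gb$W, Ugb = gb$U, bgb = gb$b,
         Ws1 = glorot(config$d_a, 2L * u),
         Ws2 = glorot(1L, config$d_a),
         wout = rnorm(2L * u, sd = sqrt(1 / (2 * u))),
         bout = 0)
  })
}

check_params <- function(params, config) {
  u <- config$u
  stopifnot(identical(dim(params$Wlf), c(4L * u, 22L)),
            identical(dim(params$Wgf), c(4L * u, 2L * u)),
            identical(dim(params$Ws1), c(config$d_a, 2L * u)),
            identical(dim(params$Ws2), c(1L, config$d_a)),
            length(params$wout) == 2L * u)
  invisible(params)
}

#' Local recurrent encoding of a fragment view
#'
#' Runs the shared local bidirectional LSTM over each encoded window's
#' `k + 2` rows and returns one summary per window: the concatenation of the
#' final forward and final backward hidden states. The local layer carries no
#' state across windows, so summaries are computed window by window.
#'
#' @param encoded List of `n` encoded `(k + 2) x 22` matrices (from
#'   [encode_windowset()]).
#' @param params Parameter list from [init_params()].
#' @param config A [model_config()].
#' @return An `n x 2u` matrix of window summaries.
#' @export
local_encode <- function(encoded, params, config) {
  stopifnot(is.list(encoded), length(encoded) >= 1L)
  shapes_ok <- vapply(encoded, function(m) {
    is.matrix(m) && nrow(m) == config$k + 2L && ncol(m) == 22L
  }, logical(1))
  if (!all(shapes_ok))
    stop("every encoded window must be a (k+2) x 22 matrix with k = ",
         config$k)
  cpp_local_forward(stack_encoded(encoded), config$k, length(encoded),
                    params, config$sweep == "state_first")
}

#' Global recurrent encoding over window summaries
#'
#' Runs the global bidirectional LSTM over the ordered window summaries and
#' returns the hidden-state matrix `H` (`n x 2u`): row `i` concatenates the
#' forward state after window `i` and the backward state after sweeping back
#' to window `i`.
#'
#' @param summaries `n x 2u` matrix from [local_encode()].
#' @inheritParams local_encode
#' @return An `n x 2u` matrix `H`.
#' @export
global_encode <- function(summaries, params, config) {
  if (!is.matrix(summaries) || ncol(summaries) != 2L * config$u)
    stop("summaries must be an n x 2u matrix with u = ", config$u)
  cpp_global_forward(summaries, params)
}

#' Self-attention annotation vector
#'
#' `A = softmax(Ws2 tanh(Ws1 H^T))`: a probability distribution over the `n`
#' windows, the model's localization signal.
#'
#' @param H `n x 2u` global hidden-state matrix.
#' @inheritParams local_encode
#' @return Numeric vector of length `n` summing to 1.
#' @export
attend <- function(H, params, config) {
  if (!is.matrix(H) || ncol(H) != 2L * config$u)
    stop("H must be n x 2u with u = ", config$u)
  if (ncol(params$Ws1) != ncol(H))
    stop("Ws1 has ", ncol(params$Ws1), " columns but H has ", ncol(H))
  e <- params$Ws2 %*% tanh(params$Ws1 %*% t(H))
  e <- drop(e)
  x <- exp(e - max(e))
  x / sum(x)
}

#' Attention penalty
#'
#' The piecewise penalty on the annotation vector: without position scores
#' (`S = NULL`) the self-focus term, the squared Frobenius norm of
#' `A A^T - I`, which for a `1 x n` annotation vector equals
#' `(sum(A^2) - 1)^2` and vanishes exactly when `A` is one-hot; with position
#' scores the position term `||S - A||^2`, which vanishes when attention
#' matches the motif-position distribution.
#'
#' @param A Annotation vector (length `n`, sums to 1).
#' @param S Optional position-score vector of the same length (from
#'   [position_scores()]).
#' @return Scalar penalty value.
#' @export
penalty <- function(A, S = NULL) {
  A <- as.numeric(A)
  if (is.null(S)) return((sum(A^2) - 1)^2)
  S <- as.numeric(S)
  if (length(S) != length(A))
    stop("S has length ", length(S), " but A has length ", length(A))
  sum((S - A)^2)
}

#' Classify a fragment view from attention and global states
#'
#' Forms the context vector `m = A H` (`1 x 2u`), maps it to a scalar logit
#' through the learned output weights, and returns the sigmoid probability of
#' the dimer class. The dimer call uses threshold 0.5.
#'
#' @param A Annotation vector of length `n`.
#' @param H `n x 2u` global hidden-state matrix.
#' @inheritParams local_encode
#' @return Probability in (0, 1).
#' @export
classify <- function(A, H, params, config) {
  A <- as.numeric(A)
  if (!is.matrix(H) || nrow(H) != length(A) || ncol(H) != 2L * config$u)
    stop("H must be length(A) x 2u")
  m <- drop(A %*% H)
  1 / (1 + exp(-(sum(m * params$wout) + params$bout)))
}

#' Forward pass over one encoded fragment view
#'
#' Composes local encoding, global encoding, attention and classification in
#' one call (native implementation; equal to composing the R-level ops).
#'
#' @inheritParams local_encode
#' @return List with `prob`, `A`, `H`, `M` (window summaries), `logit`.
#' @export
forward_view <- function(encoded, params, config) {
  cpp_forward(stack_encoded(encoded), config$k, length(encoded), params,
              config$sweep == "state_first")
}

#' Training objective over a batch of views
#'
#' The summed per-view objective: squared error `(y - p)^2` plus
#' `alpha` times the attention [penalty()]. Views with position scores use
#' the position term, all others the self-focus term.
#'
#' @param views List of views; each a list with `X` (stacked encoded windows,
#'   `n (k + 2) x 22`), `S` (position scores or `NULL`) and `y` (0/1 label).
#' @inheritParams local_encode
#' @return Scalar loss (sum over the batch).
#' @export
gltm_loss <- function(views, params, config) {
  if (any(vapply(views, function(v) is.na(v$y), logical(1))))
    stop("training batch contains a view with unknown label")
  res <- cpp_batch_loss_grad(views, config$k, config$n, params,
                             config$sweep == "state_first", config$alpha)
  res$loss
}

make_view <- function(frag, params_config, label_num = NULL) {
  ws <- segment_windows(frag, params_config$n, params_config$k)
  enc <- encode_windowset(frag, ws)
  ctr <- motif_center(frag)
  S <- if (!is.na(ctr)) position_scores(ws, ctr, params_config$c) else NULL
  y <- if (!is.null(label_num)) label_num else switch(frag$label,
    dimer = 1, `non-dimer` = 0, NA_real_)
  list(X = stack_encoded(enc), S = S, y = y, ws = ws)
}

flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(theta, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    piece <- theta[(pos + 1L):(pos + len)]
    if (is.matrix(template[[nm]]))
      piece <- matrix(piece, nrow(template[[nm]]), ncol(template[[nm]]))
    out[[nm]] <- piece
    pos <- pos + len
  }
  stopifnot(pos == length(theta))
  out
}

#' Numerical gradient of the training objective
#'
#' Central finite differences of [gltm_loss()] with respect to every
#' parameter; the independent oracle used to verify the analytic backward
#' pass. Intended for tiny models only.
#'
#' @inheritParams gltm_loss
#' @param eps Step size.
#' @return Numeric vector matching `flatten_params(params)`.
#' @export
numeric_gradient <- function(views, params, config, eps = 1e-5) {
  theta <- flatten_params(params)
  g <- numeric(length(theta))
  for (j in seq_along(theta)) {
    tp <- theta; tp[j] <- tp[j] + eps
    tm <- theta; tm[j] <- tm[j] - eps
    g[j] <- (gltm_loss(views, unflatten_params(tp, params), config) -
               gltm_loss(views, unflatten_params(tm, params), config)) /
      (2 * eps)
  }
  g
}

#' Analytic gradient of the training objective
#'
#' @inheritParams gltm_loss
#' @return List with `loss`, `probs` and `grads` (named like the parameters).
#' @export
analytic_gradient <- function(views, params, config) {
  cpp_batch_loss_grad(views, config$k, config$n, params,
                      config$sweep == "state_first", config$alpha)
}

#' Save or load a model checkpoint
#'
#' A checkpoint is a single JSON archive holding every weight matrix and the
#' full configuration used to train it.
#'
#' @param model A `gltm_model` (list with `params`, `config`, optional
#'   `history`).
#' @param path Checkpoint path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gltm_model"))
  payload <- list(
    package = "gltm", format = 1L,
    config = unclass(model$config),
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    history = model$history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  config <- model_config(k = cfg$k, n = cfg$n, u = cfg$u, d_a = cfg$d_a,
                         alpha = cfg$alpha, c = cfg$c, sweep = cfg$sweep,
                         seed = cfg$seed)
  params <- lapply(payload$params, function(p) {
    dimv <- unlist(p$dim)
    datav <- as.numeric(unlist(p$data))
    if (length(dimv) == 2L) matrix(datav, dimv[1], dimv[2]) else datav
  })
  structure(list(params = params, config = config,
                 history = payload$history, trained = TRUE),
            class = "gltm_model")
}

#' @export
print.gltm_model <- function(x, ...) {
  cat("<gltm_model>", if (isTRUE(x$trained)) "trained" else "untrained", "\n")
  print(x$config)
  if (!is.null(x$history$loss))
    cat(sprintf("epochs: %d, final loss: %.5f\n", length(x$history$loss),
                utils::tail(x$history$loss, 1)))
  invisible(x)
}
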