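make_encoded <- function(frag, cfg) {
  ws <- segment_windows(frag, cfg$n, cfg$k)
  list(ws = ws, enc = encode_windowset(frag, ws))
}

test_that("local and global encoders obey their shape/order contracts", {
  set.seed(1)
  cfg <- model_config(k = 5, n = 12, u = 4, d_a = 3, seed = 2)
  p <- init_params(cfg)
  frag <- toy_fragment()
  e <- make_encoded(frag, cfg)
  M <- local_encode(e$enc, p, cfg)
  expect_equal(dim(M), c(12L, 8L))
  # determinism
  expect_identical(M, local_encode(e$enc, p, cfg))
  # the local layer is per-window: permuting inputs permutes outputs
  perm <- c(2:1, 3:12)
  expect_equal(local_encode(e$enc[perm], p, cfg), M[perm, ])

  H <- global_encode(M, p, cfg)
  expect_equal(dim(H), c(12L, 8L))
  # the global layer is order-sensitive
  Hrev <- global_encode(M[12:1, ], p, cfg)
  expect_gt(max(abs(Hrev[12:1, ] - H)), 1e-8)
  # single-summary boundary case
  expect_equal(dim(global_encode(M[1, , drop = FALSE], p, cfg)), c(1L, 8L))

  expect_error(local_encode(list(matrix(0, 3, 22)), p, cfg), "\\(k\\+2\\)")
})

test_that("attend normalizes and matches a step-by-step oracle", {
  set.seed(2)
  cfg <- tiny_config(u = 1L, d_a = 2L, n = 2L)
  p <- init_params(cfg)
  for (trial in 1:50) {
    H <- matrix(rnorm(4), 2, 2)
    A <- attend(H, p, cfg)
    expect_equal(sum(A), 1, tolerance = 1e-12)
    expect_true(all(A > 0 & A < 1))
    # independent element-wise evaluation of the annotation formula
    e <- numeric(2)
    for (i in 1:2) {
      ti <- tanh(as.numeric(p$Ws1 %*% H[i, ]))
      e[i] <- sum(as.numeric(p$Ws2) * ti)
    }
    oracle <- exp(e) / sum(exp(e))
    expect_equal(as.numeric(A), oracle, tolerance = 1e-10)
  }
  # zero projection weights give uniform attention
  p0 <- p; p0$Ws2 <- p$Ws2 * 0
  expect_equal(as.numeric(attend(matrix(rnorm(4), 2, 2), p0, cfg)),
               c(0.5, 0.5))
})

test_that("penalty matches closed forms and an independent recomputation", {
  # self-focus: zero iff one-hot, closed form at uniform
  expect_equal(penalty(c(1, 0, 0, 0)), 0)
  expect_equal(penalty(rep(0.25, 4)), 0.5625)
  set.seed(3)
  for (trial in 1:100) {
    n <- sample(2:15, 1)
    A <- runif(n); A <- A / sum(A)
    # oracle route: treat A as a 1 x n matrix and literally evaluate
    # ||A A^T - I||_F^2 with matrix operations
    Arow <- matrix(A, nrow = 1)
    D <- Arow %*% t(Arow) - diag(1)
    expect_equal(penalty(A), sum(D^2), tolerance = 1e-8)
    expect_gt(penalty(A), 0)  # random A is never exactly one-hot
    # position term against direct element-wise sum
    S <- runif(n); S <- S / sum(S)
    direct <- sum(vapply(seq_len(n), function(i) (S[i] - A[i])^2, numeric(1)))
    expect_equal(penalty(A, S), direct, tolerance = 1e-8)
    expect_equal(penalty(S, S), 0)
  }
  # concentrating mass strictly decreases the self-focus term
  onehot <- c(1, rep(0, 3)); unif <- rep(0.25, 4)
  path <- vapply(seq(0, 1, by = 0.1),
                 function(t) penalty((1 - t) * unif + t * onehot), numeric(1))
  expect_true(all(diff(path) < 0))
  expect_error(penalty(c(0.5, 0.5), c(1, 0, 0)), "length")
})

test_that("classify selects rows under one-hot attention and stays in (0,1)", {
  set.seed(4)
  cfg <- tiny_config(n = 4L, u = 3L)
  p <- init_params(cfg)
  H <- matrix(rnorm(24), 4, 6)
  A <- c(0, 0, 1, 0)
  m <- drop(A %*% H)
  expect_equal(m, H[3, ])
  prob <- classify(A, H, p, cfg)
  expect_true(prob > 0 && prob < 1)
  p0 <- p; p0$wout <- p$wout * 0; p0$bout <- 0
  expect_equal(classify(A, H, p0, cfg), 0.5)
})

test_that("the loss equals a term-by-term recomposition from the R-level ops", {
  set.seed(5)
  cfg <- tiny_config(n = 4L, u = 2L, alpha = 0.37)
  p <- init_params(cfg)
  frag_pos <- toy_fragment("p", label = "dimer", motif_start = 8,
                           motif_end = 13)
  frag_neg <- toy_fragment("n", label = "non-dimer")
  views <- list()
  oracle <- 0
  for (frag in list(frag_pos, frag_neg)) {
    ws <- segment_windows(frag, cfg$n, cfg$k)
    enc <- encode_windowset(frag, ws)
    ctr <- motif_center(frag)
    S <- if (!is.na(ctr)) position_scores(ws, ctr) else NULL
    y <- if (frag$label == "dimer") 1 else 0
    M <- local_encode(enc, p, cfg)
    H <- global_encode(M, p, cfg)
    A <- attend(H, p, cfg)
    prob <- classify(A, H, p, cfg)
    oracle <- oracle + (y - prob)^2 + cfg$alpha * penalty(A, S)
    views <- c(views, list(list(X = do.call(rbind, enc), S = S, y = y)))
  }
  expect_equal(gltm_loss(views, p, cfg), oracle, tolerance = 1e-8)

  # alpha = 0 reduces to the pure squared error
  cfg0 <- tiny_config(n = 4L, u = 2L, alpha = 0)
  probs <- analytic_gradient(views, p, cfg0)$probs
  ys <- vapply(views, `[[`, numeric(1), "y")
  expect_equal(gltm_loss(views, p, cfg0), sum((ys - probs)^2),
               tolerance = 1e-10)

  # unknown labels are rejected
  bad <- views; bad[[1]]$y <- NA_real_
  expect_error(gltm_loss(bad, p, cfg), "unknown label")
})

test_that("penalty routing sends exactly the annotated views to the position term", {
  set.seed(6)
  cfg <- tiny_config(n = 4L, u = 2L)
  frags <- rbind(toy_fragment("a", label = "dimer", motif_start = 5,
                              motif_end = 10),
                 toy_fragment("b", label = "dimer"),  # positive, unannotated
                 toy_fragment("c", label = "non-dimer"))
  views <- lapply(seq_len(3), function(i) gltm:::make_view(frags[i, ], cfg))
  has_S <- vapply(views, function(v) !is.null(v$S), logical(1))
  # only the annotated fragment gets position scores, regardless of label
  expect_identical(has_S, c(TRUE, FALSE, FALSE))
})

test_that("analytic gradients match finite differences on a tiny model", {
  set.seed(7)
  cfg <- tiny_config(n = 3L, u = 2L, d_a = 3L, alpha = 0.1)
  p <- init_params(cfg)
  frag_pos <- toy_fragment("p", label = "dimer", motif_start = 10,
                           motif_end = 15)
  frag_neg <- toy_fragment("n", label = "non-dimer")
  v1 <- gltm:::make_view(frag_pos, cfg)[c("X", "S", "y")]
  v2 <- gltm:::make_view(frag_neg, cfg)[c("X", "y")]
  views <- list(v1, v2)
  ag <- unlist(analytic_gradient(views, p, cfg)$grads, use.names = FALSE)
  ng <- numeric_gradient(views, p, cfg)
  denom <- pmax(abs(ng), 1e-4)
  expect_lt(max(abs(ag - ng) / denom), 1e-4)
})

test_that("training is reproducible and learns a separable toy task", {
  set.seed(8)
  frags <- separable_set(25, 25)
  cfg <- model_config(k = 5, n = 12, u = 16, d_a = 8, alpha = 0.1, seed = 1)
  tc <- train_config(epochs = 80, lr = 5e-3, seed = 11)
  m <- train(frags, cfg, tc)
  expect_true(all(is.finite(m$history$loss)))
  expect_lt(utils::tail(m$history$loss, 1), m$history$loss[1])
  pred <- predict_fragments(m, frags, runs = 5)
  expect_equal(mean(pred$predicted_label == frags$label), 1.0)

  # same seed -> identical parameters; also exercises checkpoint round-trip
  m2 <- train(frags, cfg, train_config(epochs = 3, seed = 11))
  m3 <- train(frags, cfg, train_config(epochs = 3, seed = 11))
  expect_equal(m2$params, m3$params, tolerance = 1e-15)

  path <- withr::local_tempfile(fileext = ".json")
  save_model(m2, path)
  m2b <- load_model(path)
  expect_equal(m2b$params, m2$params, tolerance = 1e-12)
  expect_equal(m2b$config$alpha, cfg$alpha)

  # unknown labels are rejected up front
  bad <- frags; bad$label[1] <- "unknown"
  expect_error(train(bad, cfg, tc), "unknown")
})
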