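test_that("segment_windows fixes the terminal windows and draws the interior", {
  set.seed(1)
  ws <- segment_windows(40L, n = 12, k = 5)
  expect_s3_class(ws, "gltm_windows")
  expect_length(ws$starts, 12)
  expect_equal(ws$starts[1], 0L)
  expect_equal(ws$starts[12], 35L)  # last window [35, 40)
  expect_true(all(diff(ws$starts) > 0))
  expect_true(all(ws$starts >= 0 & ws$starts + 5 <= 40))
  expect_equal(ws$centers, ws$starts + 2)

  # infeasible combinations are rejected with the constraint spelled out
  expect_error(segment_windows(40L, n = 2, k = 40), "L - k >= n - 1")
  expect_error(segment_windows(40L, n = 37, k = 5), "L - k >= n - 1")
  expect_error(segment_windows(40L, n = 1, k = 5), "n must be >= 2")

  set.seed(7); a <- segment_windows(40L, 12, 5)
  set.seed(7); b <- segment_windows(40L, 12, 5)
  expect_identical(a$starts, b$starts)
})

test_that("repeated segmentation yields many distinct views", {
  set.seed(3)
  sets <- replicate(100, paste(segment_windows(40L, 12, 5)$starts,
                               collapse = ","))
  expect_gte(length(unique(sets)), 2)
  # in practice nearly all draws differ; this is the stochasticity the
  # model's data enhancement relies on
  expect_gte(length(unique(sets)), 90)
})

test_that("encode_window matches an independent oracle encoder", {
  set.seed(4)
  for (trial in 1:25) {
    k <- sample(4:8, 1)
    seq <- random_sequence(k, AA20)
    np <- sample(0:k, 1); nn <- sample(0:k, 1)
    prev <- if (np > 0) sort(sample(0:(k - 1), np)) else integer(0)
    nxt <- if (nn > 0) sort(sample(0:(k - 1), nn)) else integer(0)
    expect_equal(encode_window(seq, prev, nxt),
                 oracle_encode_window(seq, prev, nxt))
  }

  # degenerate no-overlap case: state rows all zero, residue rows sum to 1
  m <- encode_window("GLIVA")
  expect_equal(dim(m), c(7, 22))
  expect_true(all(m[6:7, ] == 0))
  expect_equal(rowSums(m[1:5, ]), rep(1, 5))

  # documented example: two shared positions with the previous window
  m2 <- encode_window("GLIVA", overlap_prev = c(0, 1))
  expect_equal(m2[1:2, 21], c(1, 1))
  expect_equal(m2[6, 21], 0.4)

  expect_error(encode_window("GLIVA", overlap_prev = 5), "0..k-1")
})

test_that("encode_windowset computes neighbour overlaps correctly", {
  frag <- fragment("f", strrep("LIVAG", 8))
  ws <- structure(list(fragment_id = "f", starts = c(0L, 3L, 35L), k = 5L,
                       n = 3L, L = 40L, centers = c(0, 3, 35) + 2),
                  class = "gltm_windows")
  enc <- encode_windowset(frag, ws)
  expect_length(enc, 3)
  # windows [0,5) and [3,8): shared residues 3,4 -> local 3,4 of window 1,
  # local 0,1 of window 2
  expect_equal(which(enc[[1]][1:5, 22] == 1) - 1L, c(3L, 4L))
  expect_equal(which(enc[[2]][1:5, 21] == 1) - 1L, c(0L, 1L))
  # disjoint neighbours ([3,8) vs [35,40)): overlap channels all zero
  expect_true(all(enc[[2]][, 22] == 0))
  expect_true(all(enc[[3]][, 21] == 0))

  # overlap symmetry across random window sets
  set.seed(5)
  frag2 <- toy_fragment()
  for (trial in 1:10) {
    ws2 <- segment_windows(frag2, 12, 5)
    e <- encode_windowset(frag2, ws2)
    for (i in 1:11)
      expect_equal(sum(e[[i]][1:5, 22]), sum(e[[i + 1]][1:5, 21]))
  }
})

test_that("the fast view builder reproduces the public segmentation + encoding", {
  set.seed(8)
  for (trial in 1:10) {
    frag <- fragment("f", random_sequence(40, AA20), "dimer",
                     motif_start = 12, motif_end = 17)
    n <- sample(9:12, 1); k <- sample(5:7, 1)
    set.seed(100 + trial)
    ws <- segment_windows(frag, n, k)
    slow_X <- do.call(rbind, encode_windowset(frag, ws))
    slow_S <- position_scores(ws, motif_center(frag))
    set.seed(100 + trial)
    fast <- gltm:::fast_view(gltm:::sequence_codes(frag$sequence),
                             as.integer(n), as.integer(k), 14.5, 1)
    expect_identical(fast$X, slow_X)
    expect_equal(fast$S, slow_S, tolerance = 1e-15)
    expect_identical(fast$starts, ws$starts)
  }
})

test_that("position scores follow the softmax of negative center distance", {
  ws <- structure(list(starts = c(0L, 1L, 2L), k = 5L, n = 3L, L = 40L,
                       centers = c(2, 3, 4)), class = "gltm_windows")
  # centers at distances 0, 1, 2 from the motif center
  s <- position_scores(ws, center = 2, c = 0)
  expect_equal(s, c(0.66524096, 0.24472847, 0.09003057), tolerance = 1e-7)
  expect_equal(sum(s), 1)
  expect_equal(which.max(s), 1)

  # c provably cancels
  for (cc in c(-5, 5, 7))
    expect_lt(max(abs(position_scores(ws, 2, cc) - s)), 1e-12)

  # single window: trivially all the mass
  ws1 <- structure(list(starts = 0L, k = 5L, n = 1L, L = 5L, centers = 2),
                   class = "gltm_windows")
  expect_equal(position_scores(ws1, 2), 1)

  expect_error(position_scores(ws, NA_real_), "unannotated")
})

test_that("position scores peak at the window nearest the motif center", {
  set.seed(6)
  for (trial in 1:20) {
    ws <- segment_windows(40L, 12, 5)
    ctr <- runif(1, 0, 39)
    s <- position_scores(ws, ctr)
    expect_equal(sum(s), 1, tolerance = 1e-12)
    expect_true(all(s > 0))
    expect_equal(which.max(s), which.min(abs(ws$centers - ctr)))
  }
})
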