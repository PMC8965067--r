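# a small trained model shared by the localization tests
local_model <- local({
  set.seed(31)
  frags <- separable_set(25, 25)
  cfg <- model_config(k = 5, n = 12, u = 16, d_a = 8, alpha = 0.1, seed = 1)
  train(frags, cfg, train_config(epochs = 50, lr = 5e-3, seed = 13))
})

test_that("vote tiers follow the GLTM tier thresholds and are nested", {
  votes <- c(0, 1, 5, 6, 10, 11, 20)
  expect_equal(vote_tier(votes),
               c("none", "blue", "blue", "orange", "orange", "red", "red"))
  # monotone: more votes never lowers the tier
  ranks <- c(none = 0, blue = 1, orange = 2, red = 3)
  expect_true(all(diff(ranks[vote_tier(0:20)]) >= 0))
})

test_that("locate conserves votes and respects the call threshold", {
  set.seed(32)
  frag <- separable_set(1, 0)
  res <- locate(local_model, frag, runs = 20)
  expect_s3_class(res, "gltm_localization")
  expect_equal(sum(res$run_dimer), res$dimer_votes)
  # each dimer-called run adds exactly k residue votes
  expect_equal(sum(res$residue_votes), res$dimer_votes * 5)
  expect_true(all(res$residue_votes <= res$dimer_votes))
  expect_equal(res$true_times,
               sum(res$run_dimer == (frag$label == "dimer")))
  expect_identical(res$tiers, vote_tier(res$residue_votes))
  expect_equal(nchar(render_tiers(res)), 40)

  # a fragment never called dimer collects no votes at all
  set.seed(33)
  neg <- separable_set(0, 1)
  rneg <- locate(local_model, neg, runs = 20)
  if (rneg$dimer_votes == 0) {
    expect_true(all(rneg$residue_votes == 0))
    expect_true(all(rneg$tiers == "none"))
  }

  untrained <- structure(list(params = init_params(local_model$config),
                              config = local_model$config, trained = FALSE),
                         class = "gltm_model")
  expect_error(locate(untrained, frag), "untrained")
})

test_that("locate is deterministic under a fixed seed", {
  frag <- separable_set(1, 0)
  set.seed(34); a <- locate(local_model, frag, runs = 10)
  set.seed(34); b <- locate(local_model, frag, runs = 10)
  expect_identical(a$residue_votes, b$residue_votes)
  expect_identical(a$run_starts, b$run_starts)
})

test_that("a trained model recovers planted motifs above the random-choice baseline", {
  set.seed(35)
  test_frags <- separable_set(20, 0)
  results <- locate_all(local_model, test_frags, runs = 20)
  ev <- evaluate_localization(results, test_frags)
  expect_true(all(ev$recovery[c("blue", "orange")] >= ev$recovery["red"],
                  na.rm = TRUE))

  # Monte-Carlo chance baseline: random window choice with every run called
  # dimer; red recovery (>10 votes intersecting a 5-residue motif) is rare
  chance <- local({
    set.seed(36)
    hits <- replicate(300, {
      interval <- c(10, 15)
      votes <- integer(40)
      for (r in 1:20) {
        ws <- segment_windows(40L, 12, 5)
        b <- sample.int(12, 1)
        span <- (ws$starts[b] + 1):(ws$starts[b] + 5)
        votes[span] <- votes[span] + 1L
      }
      reg <- which(votes > 10) - 1L
      any(reg >= interval[1] & reg < interval[2])
    })
    mean(hits)
  })
  expect_gt(ev$recovery["red"], chance + 0.3)
})

test_that("evaluate_localization implements the recovery definitions", {
  mk_res <- function(id, votes, predicted = "dimer") {
    structure(list(fragment_id = id, predicted_label = predicted,
                   true_times = NA_integer_, dimer_votes = 20L,
                   residue_votes = votes, tiers = vote_tier(votes),
                   run_starts = rep(which.max(votes) - 1L, 20),
                   run_centers = rep(which.max(votes) + 1, 20),
                   run_dimer = rep(TRUE, 20),
                   run_interior = rep(TRUE, 20),
                   runs = 20L, k = 5L, L = 40L),
              class = "gltm_localization")
  }
  frags <- rbind(fragment("a", strrep("L", 40), "dimer", 10, 15),
                 fragment("b", strrep("L", 40), "dimer", 30, 35))
  # fragment a: red region covers the true interval; b: red region elsewhere
  va <- integer(40); va[11:15] <- 12L
  vb <- integer(40); vb[1:5] <- 12L
  ev <- evaluate_localization(list(mk_res("a", va), mk_res("b", vb)), frags)
  expect_equal(unname(ev$recovery["red"]), 0.5)
  # when every red region covers its interval the rate is 1
  vb2 <- integer(40); vb2[31:35] <- 12L
  ev2 <- evaluate_localization(list(mk_res("a", va), mk_res("b", vb2)), frags)
  expect_equal(unname(ev2$recovery["red"]), 1.0)
  # non-dimer predictions are excluded from recovery
  ev3 <- evaluate_localization(list(mk_res("a", va),
                                    mk_res("b", vb, "non-dimer")), frags)
  expect_equal(unname(ev3$recovery["red"]), 1.0)
})

test_that("classification metrics follow the standard definitions", {
  pred <- c(rep("dimer", 6), rep("non-dimer", 14))
  truth <- c(rep("dimer", 5), "non-dimer", "dimer", rep("non-dimer", 13))
  ev <- evaluate_classification(pred, truth)
  expect_equal(ev$tp, 5); expect_equal(ev$fp, 1)
  expect_equal(ev$fn, 1); expect_equal(ev$tn, 13)
  expect_equal(ev$accuracy, 0.9)
  expect_equal(ev$precision, 5 / 6)
  expect_equal(ev$recall, 5 / 6)

  expect_warning(
    ev0 <- evaluate_classification(rep("non-dimer", 4),
                                   c("dimer", rep("non-dimer", 3))),
    "precision")
  expect_equal(ev0$precision, 0)

  expect_error(evaluate_classification(character(0), character(0)), "empty")
})
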