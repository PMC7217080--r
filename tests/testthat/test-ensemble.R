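# helper: build a one-split stump object directly, bypassing fitting
mk_stump <- function(id, thr, lc, rc, lp, rp) {
  structure(list(scale_id = id, threshold = thr, left_class = lc,
                 right_class = rc, left_prob = lp, right_prob = rp,
                 is_leaf_only = FALSE, training_accuracy = max(lp, rp),
                 n = 10L),
            class = "decision_stump")
}

mk_model <- function(stumps, k = length(stumps)) {
  structure(list(stumps = stumps,
                 importance = vapply(stumps, `[[`, numeric(1),
                                     "training_accuracy"),
                 scale_ids = vapply(stumps, `[[`, character(1), "scale_id"),
                 k = k, n_train = 10L, trim_n = NULL, trim_c = NULL),
            class = "sevc")
}

test_that("a one-scale ensemble is its stump", {
  x <- matrix(c(0, 1, 2, 3), ncol = 1, dimnames = list(NULL, "S1"))
  y <- c(0, 0, 1, 1)
  fit <- sevc(x, y)
  expect_equal(length(fit$stumps), 1L)
  expect_equal(fit$importance, fit$stumps[[1]]$training_accuracy)
  v <- soft_vote(fit, c(S1 = 2.5), k = 1)
  p <- stump_predict(fit$stumps[[1]], 2.5)
  expect_equal(v$class, p$class)
  expect_equal(max(v$score0, v$score1), p$prob)
})

test_that("feature selection sorts stumps by training accuracy, stable on ties", {
  set.seed(2)
  y <- rep(c(0, 1), each = 10)
  x <- cbind(noisy = stats::rnorm(20) + 0.5 * y, perfect = y)
  fit <- sevc(x, y)
  expect_identical(fit$scale_ids[1], "perfect")
  expect_true(all(diff(fit$importance) <= 0))

  # ten-scale matrix: ordering equals an independent recompute-and-sort
  sim <- small_sim()
  lib <- example_scale_library()
  fm <- build_feature_matrix(sim$dataset, lib)
  yy <- sim$dataset$records$label
  fit10 <- sevc(fm, yy)
  acc <- vapply(seq_len(ncol(fm)), function(j)
    fit_stump(fm[, j], yy)$training_accuracy, numeric(1))
  ord <- order(-acc)   # stable, library order on ties
  expect_identical(fit10$scale_ids, colnames(fm)[ord])
  expect_equal(fit10$importance, acc[ord])
})

test_that("soft votes sum decided-class probabilities only", {
  # stump votes: (class 1, p 0.9) and (class 0, p 0.6) at feature 1
  s1 <- mk_stump("a", 0, 0L, 1L, 0.9, 0.9)
  s2 <- mk_stump("b", 2, 0L, 1L, 0.6, 0.6)
  m <- mk_model(list(s1, s2))
  v <- soft_vote(m, c(a = 1, b = 1))
  expect_equal(v$class, 1L)
  expect_equal(v$score0, 0.6)
  expect_equal(v$score1, 0.9)

  # missing feature for an included scale
  expect_error(soft_vote(m, c(a = 1)), "lacks scale")
})

test_that("soft voting equals brute-force accumulation over k stumps", {
  sim <- small_sim(seed = 21, label_noise = 0.15)
  lib <- example_scale_library()
  fm <- build_feature_matrix(sim$dataset, lib)
  y <- sim$dataset$records$label
  fit <- sevc(fm, y)
  for (k in c(1, 3, 6, 10)) {
    pred <- predict(fit, fm, k = k)
    for (i in c(1, 17, 48)) {
      s0 <- 0; s1 <- 0
      for (j in seq_len(k)) {
        st <- fit$stumps[[j]]
        p <- stump_predict(st, fm[i, st$scale_id])
        if (p$class == 1) s1 <- s1 + p$prob else s0 <- s0 + p$prob
      }
      expect_equal(pred$score0[i], s0)
      expect_equal(pred$score1[i], s1)
      expect_equal(pred$class[i], as.integer(s1 > s0))
    }
    # score bounds: probabilities are at most 1 each
    expect_true(all(pred$score0 + pred$score1 <= k + 1e-12))
    expect_true(all(pmax(pred$score0, pred$score1) <= k + 1e-12))
  }
})

test_that("hard voting is a majority count with ties to insoluble", {
  s1 <- mk_stump("a", 0, 0L, 1L, 0.8, 0.8)
  s2 <- mk_stump("b", 0, 0L, 1L, 0.7, 0.7)
  s3 <- mk_stump("c", 5, 0L, 1L, 0.9, 0.9)
  m <- mk_model(list(s1, s2, s3))
  # at feature 1: votes {1, 1, 0} -> majority 1
  expect_equal(hard_vote(m, c(a = 1, b = 1, c = 1)), 1L)
  # two stumps, votes {1, 0}: tie -> class 0
  expect_equal(hard_vote(mk_model(list(s1, s3)), c(a = 1, c = 1)), 0L)

  # counting oracle on a fitted ensemble
  sim <- small_sim(seed = 31, label_noise = 0.15)
  lib <- example_scale_library()
  fm <- build_feature_matrix(sim$dataset, lib)
  fit <- sevc(fm, sim$dataset$records$label)
  hv <- predict(fit, fm, k = 10, vote = "hard")
  votes1 <- rowSums(vapply(fit$stumps, function(st)
    predict(st, fm[, st$scale_id])$class, numeric(48)))
  expect_equal(hv$class, as.integer(votes1 > 10 - votes1))
})

test_that("dataset prediction is the row-wise soft vote", {
  sim <- small_sim(seed = 41)
  lib <- example_scale_library()
  fm <- build_feature_matrix(sim$dataset, lib)
  fit <- sevc(fm, sim$dataset$records$label, k = 4)
  pd <- predict_dataset(fit, fm)
  expect_equal(nrow(pd), nrow(fm))
  for (i in c(2, 30)) {
    v <- soft_vote(fit, fm[i, ], k = 4)
    expect_equal(pd$class[i], v$class)
    expect_equal(pd$score1[i], v$score1)
  }
  # duplicated rows predict identically
  fm2 <- fm[c(1, 1), , drop = FALSE]
  p2 <- predict(fit, fm2, k = 4)
  expect_equal(p2[1, ], p2[2, ], ignore_attr = TRUE)
  # single-row matrix works
  p1 <- predict(fit, fm[5, , drop = FALSE], k = 4)
  expect_equal(p1$class, pd$class[5])
})

test_that("with k = 1 the ensemble reduces to its best stump", {
  sim <- small_sim(seed = 51, label_noise = 0.1)
  lib <- example_scale_library()
  fm <- build_feature_matrix(sim$dataset, lib)
  y <- sim$dataset$records$label
  fit <- sevc(fm, y)
  pred <- predict(fit, fm, k = 1)$class
  expect_equal(mean(pred == y), fit$importance[1])
})

test_that("model JSON serialization round-trips predictions", {
  sim <- small_sim(seed = 61, label_noise = 0.1)
  lib <- example_scale_library()
  fm <- build_feature_matrix(sim$dataset, lib)
  fit <- sevc(fm, sim$dataset$records$label, k = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_sevc_json(fit, path, lib = lib)
  back <- read_sevc_json(path)
  expect_equal(back$model$scale_ids, fit$scale_ids)
  expect_equal(back$model$importance, fit$importance)
  expect_equal(predict(back$model, fm), predict(fit, fm))
  expect_equal(as.matrix(back$lib), as.matrix(lib))
})

test_that("summary ranks tied importances with shared min-rank", {
  x <- cbind(s1 = c(0, 0, 1, 1), s2 = c(0, 0, 1, 1), s3 = c(0.1, 0, 0.2, 0))
  fit <- sevc(x, c(0, 0, 1, 1))
  sm <- summary(fit)
  expect_equal(sm$rank[1:2], c(1L, 1L))
  expect_identical(sm$scale_id[1:2], c("s1", "s2"))  # library order on ties
})
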