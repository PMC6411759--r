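test_that("forest training is reproducible and separates separable data", {
  set.seed(3)
  lab <- random_labels(40, 20)
  x <- cbind(indicator = as.numeric(lab == "positive"),
             noise1 = rnorm(40), noise2 = rnorm(40))
  f1 <- train_forest(x, lab, n_trees = 100, seed = 5)
  f2 <- train_forest(x, lab, n_trees = 100, seed = 5)
  s1 <- predict(f1, x); s2 <- predict(f2, x)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(roc_auc(s1, lab)$auc, 1)    # resubstitution on separable data
  expect_error(train_forest(x, rep("positive", 40)), "each class")
  xna <- x; xna[1, 1] <- NA
  expect_error(train_forest(xna, lab), "non-finite")
  expect_error(predict(f1, x[, 1:2]), "dimension mismatch")
})

test_that("forest defaults follow the published configuration", {
  lab <- random_labels(12, 6)
  x <- matrix(rnorm(12 * 9), 12)
  f <- train_forest(x, lab, seed = 1)
  expect_equal(f$n_trees, 1000L)
  expect_equal(f$mtry, 3L)                 # floor(sqrt(9))
  expect_equal(f$forest$forest$num.trees, 1000)
})

test_that("ensemble weights validate the simplex constraints", {
  w <- ensemble_weights(c(0, 0, 0.15, 0.25, 0.6))
  expect_equal(names(w), encoder_names())
  expect_error(ensemble_weights(c(0.5, 0.5, 0, 0, 0.1)), "sum to 1")
  expect_error(ensemble_weights(c(-0.1, 0.4, 0.3, 0.2, 0.2)), "non-negative")
  expect_error(ensemble_weights(c(0.5, 0.5)), "5 weights")
})

test_that("score fusion is the published weighted sum and is monotone", {
  w <- c(0, 0, 0.15, 0.25, 0.6)
  expect_equal(combine_scores(c(0.5, 0.5, 0.2, 0.4, 0.8), w), 0.61)
  ## one-hot weights return that encoder's score unchanged
  expect_equal(combine_scores(c(0.1, 0.2, 0.3, 0.4, 0.7),
                              c(0, 0, 0, 0, 1)), 0.7)
  ## zero-weight encoders may be NA
  expect_equal(combine_scores(c(NA, NA, 0.2, 0.4, 0.8), w), 0.61)
  expect_error(combine_scores(c(0.5, 0.5, 1.2, 0.4, 0.8), w), "\\[0, 1\\]")
  expect_error(combine_scores(c(NA, 0.5, NA, 0.4, 0.8), w), "NA score")
  ## monotone: raising any single active score never lowers the combination
  set.seed(6)
  for (i in 1:20) {
    s <- runif(5)
    j <- sample(3:5, 1)
    s2 <- s; s2[j] <- min(1, s[j] + runif(1) * (1 - s[j]))
    expect_gte(combine_scores(s2, w), combine_scores(s, w))
  }
})

test_that("the weight lattice enumerates the full simplex grid in order", {
  lat <- weight_lattice(5, 0.05)
  expect_equal(nrow(lat), choose(24, 4))   # compositions of 20 into 5 parts
  expect_equal(rowSums(lat), rep(1, nrow(lat)))
  expect_true(all(lat >= 0))
  expect_equal(lat[1, ], c(0, 0, 0, 0, 1))  # lexicographic start
  expect_equal(lat[nrow(lat), ], c(1, 0, 0, 0, 0))
  expect_false(any(duplicated(lat)))
  small <- weight_lattice(2, 0.5)
  expect_equal(small, rbind(c(0, 1), c(0.5, 0.5), c(1, 0)), ignore_attr = TRUE)
})

test_that("grid search finds the informative encoder and breaks ties first", {
  set.seed(44)
  lab <- random_labels(60, 30)
  informative <- as.numeric(lab == "positive") * 0.8 + 0.1
  m <- cbind(SPIDER2 = 0.5, PEP2D = 0.5, KSAAP = 0.5,
             AAindex = informative, pKSAAP = 0.5)
  w <- grid_search_weights(m, lab)
  expect_equal(attr(w, "auc"), 1)
  expect_equal(attr(w, "n_candidates"), choose(24, 4))
  expect_gt(w[["AAindex"]], 0)
  ## five identical columns: every candidate ties; first in enumeration wins
  same <- matrix(runif(60), 60, 5)
  w2 <- grid_search_weights(same, lab)
  expect_equal(as.numeric(w2), c(0, 0, 0, 0, 1))
  ## NA columns are constrained to zero weight
  m2 <- m; m2[, c(1, 2)] <- NA
  w3 <- grid_search_weights(m2, lab)
  expect_equal(unname(w3[1:2]), c(0, 0))
  expect_error(grid_search_weights(m, rep("positive", 60)), "both classes")
})

test_that("grid search never loses to a single-encoder one-hot", {
  set.seed(47)
  lab <- random_labels(80, 40)
  m <- matrix(runif(80 * 5), 80, 5)
  m[, 3] <- m[, 3] + as.numeric(lab == "positive")  # one informative column
  m <- m / max(m)
  w <- grid_search_weights(m, lab)
  onehots <- vapply(1:5, function(j) roc_auc(m[, j], lab)$auc, numeric(1))
  expect_gte(attr(w, "auc"), max(onehots))
})

test_that("threshold calibration attains each specificity target in order", {
  ## separable scores: any cutoff in (0, 1] gives Sp = 1
  lab <- rep(c("positive", "negative"), each = 10)
  th <- calibrate_thresholds(c(rep(1, 10), rep(0, 10)), lab)
  expect_equal(th$achieved_sp, rep(1, 3))
  expect_true(all(th$cutoff > 0 & th$cutoff <= 1))

  ## hand-derived: negatives at 0.1..1.0, target 0.9 -> cutoff 1.0
  sc <- c(seq(0.1, 1, 0.1), rep(1, 5))
  lb <- rep(c("negative", "positive"), c(10, 5))
  th2 <- calibrate_thresholds(sc, lb, sp_targets = c(high = 0.9))
  expect_equal(th2$cutoff, 1.0)
  expect_equal(th2$achieved_sp, 0.9)

  ## ordering: cutoffs and achieved Sp non-increasing from high to low
  set.seed(50)
  sc3 <- runif(200)
  lb3 <- random_labels(200, 100)
  th3 <- calibrate_thresholds(sc3, lb3)
  expect_true(all(diff(th3$cutoff) <= 0))
  expect_true(all(diff(th3$achieved_sp) <= 0))
  expect_true(all(th3$achieved_sp >= th3$target_sp))

  ## unattainable without predicting everything negative -> warning
  expect_warning(
    thw <- calibrate_thresholds(c(1, 1, 1, 0.5), rep(c("negative", "positive"), 2),
                                sp_targets = c(high = 0.9)),
    "negative")
  expect_gt(thw$cutoff, 1)
})

test_that("trained model predicts with monotone three-level calls", {
  ds <- tiny_dataset(15, effect = 4, seed = 19)
  model <- aip_train(ds, encoders = c("KSAAP", "AAindex"),
                     n_trees = 60, folds = 3, seed = 19)
  expect_s3_class(model, "aip_model")
  expect_equal(sum(model$weights), 1)
  expect_true(all(as.numeric(model$weights) %in% seq(0, 1, 0.05)))
  newds <- tiny_dataset(8, effect = 4, seed = 77)
  preds <- predict(model, newds)
  expect_equal(nrow(preds), 16L)
  expect_true(all(is.na(preds$SPIDER2)))
  expect_true(all(preds$call_high <= preds$call_moderate))
  expect_true(all(preds$call_moderate <= preds$call_low))
  ## calls agree with the cutoffs row by row
  cuts <- setNames(model$thresholds$cutoff, model$thresholds$level)
  expect_equal(preds$call_high, preds$combined >= cuts[["high"]])
  ## positives tend to outscore the negatives' median
  med_neg <- median(preds$combined[newds$label == "negative"])
  expect_gt(mean(preds$combined[newds$label == "positive"] > med_neg), 0.5)
})

test_that("model bundles round-trip through disk", {
  ds <- tiny_dataset(12, effect = 4, seed = 23)
  model <- aip_train(ds, encoders = "KSAAP", n_trees = 50, folds = 3,
                     seed = 23)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  preds1 <- predict(model, ds)
  preds2 <- predict(back, ds)
  expect_identical(preds1, preds2)
})

test_that("end-to-end training is deterministic under a fixed master seed", {
  ds <- tiny_dataset(12, effect = 3, seed = 29)
  m1 <- aip_train(ds, encoders = c("KSAAP", "AAindex"), n_trees = 50,
                  folds = 3, seed = 4)
  m2 <- aip_train(ds, encoders = c("KSAAP", "AAindex"), n_trees = 50,
                  folds = 3, seed = 4)
  expect_identical(m1$oof_scores, m2$oof_scores)
  expect_identical(as.numeric(m1$weights), as.numeric(m2$weights))
  expect_identical(m1$thresholds$cutoff, m2$thresholds$cutoff)
})
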