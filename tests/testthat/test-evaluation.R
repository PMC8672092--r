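test_that("confusion counts follow the positive = virion-protein convention", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fn + perfect$fp, 0)
  expect_error(confusion_counts(c(1, 0), c(1)), "equal-length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0 or 1")
  set.seed(44)
  for (r in 1:20) {
    n <- sample(1:50, 1)
    cc <- confusion_counts(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, n)
  }
})

test_that("Sn/Sp/ACC/MCC evaluate their formulas exactly", {
  m <- classification_metrics(list(tp = 89, fn = 11, fp = 8, tn = 192))
  expect_equal(m$sn, 0.89)
  expect_equal(m$sp, 0.96)
  expect_equal(m$acc, 281 / 300)
  expect_gt(m$mcc, 0)
  perfect <- classification_metrics(list(tp = 5, fn = 0, fp = 0, tn = 5))
  expect_equal(unlist(perfect[c("sn", "sp", "acc", "mcc")]),
               c(sn = 1, sp = 1, acc = 1, mcc = 1))
  # everything predicted positive on mixed truth: Sp 0, MCC 0 by convention
  allpos <- classification_metrics(confusion_counts(c(1, 1, 0), c(1, 1, 1)))
  expect_equal(allpos$sp, 0)
  expect_equal(allpos$mcc, 0)
  expect_error(classification_metrics(list(tp = 0, fn = 0, fp = 0, tn = 0)),
               "zero")
})

test_that("metrics agree with independent recomputation on random vectors", {
  set.seed(99)
  for (r in 1:1000) {
    n <- sample(2:60, 1)
    y <- rbinom(n, 1, 0.5)
    yhat <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    got <- classification_metrics(confusion_counts(y, yhat))
    want <- naive_metrics(y, yhat)
    for (f in c("sn", "sp", "acc", "mcc")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    }
  }
})

test_that("MCC is invariant under relabelling both truth and prediction", {
  set.seed(61)
  for (r in 1:50) {
    y <- rbinom(30, 1, 0.5); yhat <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- classification_metrics(confusion_counts(y, yhat))$mcc
    b <- classification_metrics(confusion_counts(1 - y, 1 - yhat))$mcc
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("holdout split is stratified, seeded and partitions the input", {
  labels <- rep(c(1L, 0L), c(99, 208))
  sp <- holdout_split(labels, 0.8, seed = 5)
  expect_equal(sum(labels[sp$train] == 1), 79)  # round(0.8 * 99)
  expect_equal(sum(labels[sp$train] == 0), 166) # round(0.8 * 208)
  expect_equal(sum(labels[sp$test] == 1), 20)
  expect_equal(sum(labels[sp$test] == 0), 42)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(holdout_split(labels, 0.8, seed = 5), sp)
  half <- holdout_split(c(1L, 1L, 0L, 0L), 0.5, seed = 1)
  expect_equal(length(half$train), 2)
  expect_error(holdout_split(labels, 0), "between 0 and 1")
  expect_error(holdout_split(rep(1L, 10), 0.5), "both classes")
})

small_cfg <- function(...) {
  pvp_config(k = 1, use_188d = TRUE, epochs = 200, ...)
}

test_that("cross-validation pools counts over a true partition and is seeded", {
  fx <- generate_fixture(fixture_spec(20, 20, c(30, 60),
                                      pos_weights = c(W = 6, H = 6), seed = 2))
  cv <- kfold_cv(fx$seqs, fx$labels, small_cfg(), folds = 5, seed = 3)
  cc <- cv$counts
  expect_equal(cc$tp + cc$fn + cc$fp + cc$tn, 40)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(sum(cv$per_fold$n), 40)
  cv2 <- kfold_cv(fx$seqs, fx$labels, small_cfg(), folds = 5, seed = 3)
  expect_identical(cv$assignment, cv2$assignment)
  expect_identical(cv$metrics$acc, cv2$metrics$acc)
  expect_equal(cv$metrics$acc,
               (cc$tp + cc$tn) / 40)  # pooled ACC identity
  expect_error(kfold_cv(fx$seqs, fx$labels, small_cfg(), folds = 21, seed = 1),
               "stratification")
})

test_that("leave-one-out on a separable fixture is perfectly accurate", {
  fx <- generate_fixture(fixture_spec(10, 10, c(40, 60),
                                      pos_weights = c(W = 40), seed = 7))
  cv <- kfold_cv(fx$seqs, fx$labels, small_cfg(), folds = 10, seed = 1)
  expect_equal(cv$metrics$acc, 1)
  expect_equal(cv$metrics$mcc, 1)
})

test_that("holdout evaluation trains on the split and reports test metrics", {
  fx <- generate_fixture(fixture_spec(25, 25, c(30, 60),
                                      pos_weights = c(W = 10, K = 5), seed = 4))
  ho <- holdout_eval(fx$seqs, fx$labels, small_cfg(), fraction = 0.8, seed = 2)
  expect_equal(length(ho$split$train), 40)
  expect_equal(length(ho$split$test), 10)
  total <- with(ho$counts, tp + fn + fp + tn)
  expect_equal(total, 10)
  expect_gte(ho$metrics$acc, 0.8)
  expect_s3_class(ho$model, "pvp_model")
})

test_that("full-matrix selection scope is honoured and logged in the object", {
  fx <- generate_fixture(fixture_spec(15, 15, c(20, 40),
                                      pos_weights = c(W = 8), seed = 9))
  cfg <- pvp_config(k = 2, use_188d = FALSE, n_select = 10,
                    n_estimators = 10, epochs = 100,
                    selection_scope = "full")
  cv <- kfold_cv(fx$seqs, fx$labels, cfg, folds = 3, seed = 1)
  expect_equal(cv$config$selection_scope, "full")
  expect_equal(cv$counts$tp + cv$counts$fn, 15)
})
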