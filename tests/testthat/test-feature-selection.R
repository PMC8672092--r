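# planted-signal matrix: column 1 separates the classes, the rest is noise
planted_matrix <- function(n = 200, d = 51, seed = 1, gap = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  x[, 1] <- x[, 1] + gap * y
  list(x = x, y = y)
}

test_that("a perfectly separating column ranks first among noise", {
  pm <- planted_matrix(n = 200, d = 51, seed = 4, gap = 6)
  rk <- fit_adaboost_ranker(pm$x, pm$y, n_estimators = 25)
  expect_equal(rk$ranking[1], 1L)
  expect_gt(rk$scores[1], 0.5)
})

test_that("importances are a normalised distribution and constants score zero", {
  pm <- planted_matrix(n = 120, d = 20, seed = 9, gap = 2)
  pm$x[, 5] <- 3.14  # constant column: no split gain possible
  rk <- fit_adaboost_ranker(pm$x, pm$y, n_estimators = 30)
  expect_equal(sum(rk$scores), 1, tolerance = 1e-9)
  expect_true(all(rk$scores >= 0))
  expect_equal(rk$scores[5], 0)
  expect_setequal(rk$ranking, seq_len(ncol(pm$x)))
})

test_that("the ranking is deterministic for identical input", {
  pm <- planted_matrix(n = 80, d = 15, seed = 2)
  a <- fit_adaboost_ranker(pm$x, pm$y, n_estimators = 40, seed = 1)
  b <- fit_adaboost_ranker(pm$x, pm$y, n_estimators = 40, seed = 1)
  expect_identical(a$scores, b$scores)
  expect_identical(a$ranking, b$ranking)
})

test_that("degenerate inputs are refused", {
  pm <- planted_matrix(n = 40, d = 5)
  expect_error(fit_adaboost_ranker(pm$x, rep(1L, 40)), "both classes")
  bad <- pm$x; bad[3, 2] <- NA
  expect_error(fit_adaboost_ranker(bad, pm$y), "non-finite")
  expect_error(fit_adaboost_ranker(matrix(1, 10, 3), rep(c(0L, 1L), 5)),
               "constant")
})

test_that("top-n selection keeps rank order and is monotone in n", {
  pm <- planted_matrix(n = 150, d = 30, seed = 12)
  rk <- fit_adaboost_ranker(pm$x, pm$y, n_estimators = 30)
  full <- select_top(pm$x, rk, 30)
  expect_setequal(colnames(full), colnames(pm$x))
  top5 <- select_top(pm$x, rk, 5)
  top12 <- select_top(pm$x, rk, 12)
  expect_true(all(colnames(top5) %in% colnames(top12)))
  expect_equal(colnames(top12)[1:5], colnames(top5))
  expect_equal(nrow(top5), 150)
  wrong <- pm$x; colnames(wrong)[2] <- "zzz"
  expect_error(select_top(wrong, rk, 5), "do not match")
  expect_error(select_top(pm$x, rk, 31), "between 1")
})

test_that("planted informative columns are recovered near the top", {
  # c informative columns among d; all of them should sit in the top 2c
  # ranks in nearly every replicate
  hits <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    set.seed(100 + r)
    n <- 300; d <- 40; cc <- 4
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
    for (j in seq_len(cc)) x[, j] <- x[, j] + 1.5 * y
    rk <- fit_adaboost_ranker(x, y, n_estimators = 50)
    if (all(seq_len(cc) %in% rk$ranking[seq_len(2 * cc)])) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("fusion concatenates blocks and enforces the contracts", {
  a <- matrix(1:6, 2, 3, dimnames = list(c("r1", "r2"), paste0("k", 1:3)))
  b <- matrix(7:10, 2, 2, dimnames = list(c("r1", "r2"), paste0("d", 1:2)))
  ab <- combine_features(a, b)
  expect_equal(colnames(ab), c("k1", "k2", "k3", "d1", "d2"))
  # mirrors the reference fused dimensions: 260+188 and 147+188
  expect_equal(ncol(combine_features(matrix(0, 1, 260), matrix(0, 1, 188))), 448)
  expect_equal(ncol(combine_features(matrix(0, 1, 147), matrix(0, 1, 188))), 335)
  empty <- matrix(numeric(0), 2, 0, dimnames = list(c("r1", "r2"), NULL))
  expect_equal(combine_features(a, empty), a)
  bad_rows <- b; rownames(bad_rows) <- c("r2", "r1")
  expect_error(combine_features(a, bad_rows), "row ids")
  clash <- b; colnames(clash) <- c("k1", "d2")
  expect_error(combine_features(a, clash), "collision")
  expect_equal(colnames(combine_features(a, b, prefix_a = "knc_")),
               c("knc_k1", "knc_k2", "knc_k3", "d1", "d2"))
})

test_that("the ranked list serialises with its metadata header", {
  pm <- planted_matrix(n = 60, d = 8, seed = 3)
  rk <- fit_adaboost_ranker(pm$x, pm$y, n_estimators = 10, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection_tsv(rk, path)
  lines <- readLines(path)
  expect_match(lines[1], "seed=7")
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(tab), 8)
  expect_equal(tab$feature[1], rk$names[rk$ranking[1]])
})
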