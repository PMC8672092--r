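test_that("noiseless linear data is recovered to the closed-form optimum", {
  set.seed(1)
  x <- matrix(runif(50, 0, 2), 50, 1, dimnames = list(NULL, "x1"))
  y <- 0.5 + 0.25 * x[, 1]
  m <- train_sgd(x, y, alpha = 0.05, epochs = 500, seed = 1,
                 standardize = FALSE)
  expect_equal(unname(m$theta), c(0.5, 0.25), tolerance = 1e-3)
  # independent oracle: ordinary least squares has the unique optimum
  ols <- unname(coef(lm(y ~ x[, 1])))
  expect_equal(unname(m$theta), ols, tolerance = 1e-3)
})

test_that("multi-feature noiseless recovery works on well-conditioned input", {
  set.seed(8)
  x <- matrix(runif(300, 0, 1), 100, 3, dimnames = list(NULL, paste0("x", 1:3)))
  theta_star <- c(0.2, 0.3, -0.1, 0.4)
  y <- theta_star[1] + x %*% theta_star[-1]
  y <- pmin(pmax(drop(y), 0), 1)
  m <- train_sgd(x, y, alpha = 0.05, epochs = 2000, seed = 2,
                 standardize = FALSE)
  expect_equal(unname(m$theta), theta_star, tolerance = 1e-3)
})

test_that("hyperparameter preconditions are enforced", {
  x <- matrix(rnorm(20), 10, 2)
  y <- rep(c(0, 1), 5)
  expect_error(train_sgd(x, y, alpha = 0), "alpha")
  expect_error(train_sgd(x, y, alpha = -1), "alpha")
  expect_error(train_sgd(x, y, epochs = 0), "epochs")
  expect_error(train_sgd(x, c(rep(0, 9), 2)), "\\[0, 1\\]")
  bad <- x; bad[1, 1] <- Inf
  expect_error(train_sgd(bad, y), "non-finite")
})

test_that("fits are bitwise-deterministic per seed and vary across seeds", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4)
  y <- as.numeric(x[, 1] > 0)
  a <- train_sgd(x, y, epochs = 50, seed = 10)
  b <- train_sgd(x, y, epochs = 50, seed = 10)
  c_ <- train_sgd(x, y, epochs = 50, seed = 11)
  expect_identical(a$theta, b$theta)
  expect_false(identical(a$theta, c_$theta))
})

test_that("decision values are the affine score and match a dot product", {
  set.seed(6)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rep(c(0, 1), 5)
  m <- train_sgd(x, y, epochs = 5, seed = 1, standardize = FALSE)
  # oracle: explicit bias + dot product per row
  manual <- apply(x, 1, function(r) m$theta[1] + sum(m$theta[-1] * r))
  expect_equal(decision_value(m, x), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
  m0 <- m; m0$theta[] <- 0
  expect_equal(unname(decision_value(m0, x)), rep(0, 10))
  m2 <- m; m2$theta <- c(1, 2, 0, 0); names(m2$theta) <- names(m$theta)
  expect_equal(unname(decision_value(m2, x[1, , drop = FALSE])),
               unname(1 + 2 * x[1, 1]))
  expect_error(decision_value(m, x[, 1:2]), "expects 3")
})

test_that("thresholding classifies ties as positive and flags column mismatch", {
  x <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, "x1"))
  m <- train_sgd(x, c(0, 1), epochs = 5, seed = 1)
  m$theta <- c(0.5, 0); m$center <- 0; m$scale <- 1
  expect_equal(predict(m, x), c(1L, 1L))  # score exactly at threshold
  m$theta <- c(0, 1)
  expect_equal(predict(m, matrix(c(0.2, 0.9), 2, 1,
                                 dimnames = list(NULL, "x1"))), c(0L, 1L))
  xm <- x; colnames(xm) <- "other"
  expect_error(predict(m, xm), "missing: x1")
})

test_that("separable classes are fit to perfect training accuracy", {
  set.seed(21)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  x[, 1] <- x[, 1] + ifelse(y == 1, 3, -3)  # margin well beyond noise
  m <- train_sgd(x, y, alpha = 0.01, epochs = 300, seed = 4)
  expect_equal(mean(predict(m, x) == y), 1)
})

test_that("epoch-wise squared loss is non-increasing at a stable rate", {
  set.seed(13)
  x <- matrix(runif(200, 0, 1), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- pmin(pmax(0.3 + 0.4 * x[, 1] - 0.2 * x[, 2], 0), 1)
  m <- train_sgd(x, y, alpha = 0.005, epochs = 200, seed = 1,
                 standardize = FALSE, track_loss = TRUE)
  expect_length(m$loss_trace, 200)
  expect_true(all(diff(m$loss_trace) <= 1e-8))
})

test_that("hinge-loss variant trains and predicts on separable data", {
  set.seed(30)
  y <- rep(c(0, 1), each = 30)
  x <- matrix(rnorm(60), 60, 1, dimnames = list(NULL, "x1"))
  x[, 1] <- x[, 1] + ifelse(y == 1, 4, -4)
  m <- train_sgd(x, y, alpha = 0.01, epochs = 200, seed = 2, loss = "hinge",
                 threshold = 0)
  expect_equal(mean(predict(m, x) == y), 1)
})

test_that("model JSON round-trips decision values to double precision", {
  set.seed(2)
  x <- matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0, 1), 10)
  m <- train_sgd(x, y, epochs = 20, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_sgd_model(m, path)
  m2 <- read_sgd_model(path)
  expect_equal(decision_value(m2, x), decision_value(m, x), tolerance = 1e-12)
  expect_identical(m2$threshold, m$threshold)
  expect_identical(predict(m2, x), predict(m, x))
})
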