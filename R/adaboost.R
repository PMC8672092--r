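# column-wise cumulative sums without looping over columns
col_cumsum <- function(m) {
  n <- nrow(m); d <- ncol(m)
  v <- cumsum(as.numeric(m))
  if (d > 1L) v <- v - rep(c(0, v[n * seq_len(d - 1L)]), each = n)
  matrix(v, n, d)
}

#' Rank features by AdaBoost stump importance
#'
#' Boosts depth-1 decision stumps (discrete AdaBoost / SAMME with two
#' classes): each round finds the single-feature threshold split with the
#' lowest weighted misclassification, weights it by
#' `log((1 - err) / err)`, and re-weights the samples. A feature's
#' importance is the sum over rounds of the estimator weight times the
#' weighted Gini impurity decrease of its split, normalised to sum to 1.
#' Boosting stops early when no stump beats chance (weighted error >= 0.5)
#' or a stump is perfect. The procedure is deterministic; ties between
#' equally good splits go to the lower column index. The `seed` is recorded
#' in the model for provenance but consumes no randomness.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param labels Integer vector in \{0, 1\}, both classes present.
#' @param n_estimators Maximum number of boosting rounds (default 100).
#' @param seed Recorded metadata seed (default 1).
#'
#' @return Object of class `adaboost_ranker`: list with `names` (input
#'   column order), `scores` (importances, sum 1), `ranking` (column indices
#'   by descending score, ties by ascending index), `n_estimators`,
#'   `n_rounds` (rounds actually run) and `seed`.
#' @export
fit_adaboost_ranker <- function(x, labels, n_estimators = 100L, seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) >= 2L, n_estimators >= 1L)
  if (!all(labels %in% c(0L, 1L)) || length(labels) != nrow(x)) {
    stop("`labels` must be a 0/1 vector aligned to rows of `x`", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit the ranker", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  ord <- apply(x, 2L, order)                       # n x d row indices
  xs <- matrix(x[ord + rep((seq_len(d) - 1L) * n, each = n)], n, d)
  valid <- xs[-n, , drop = FALSE] != xs[-1L, , drop = FALSE]
  if (!any(valid)) stop("all features are constant; no split possible", call. = FALSE)

  w <- rep(1 / n, n)
  imp <- numeric(d)
  pos <- labels == 1L
  rounds <- 0L
  for (m in seq_len(n_estimators)) {
    wp <- w * pos
    wn <- w - wp
    tot_p <- sum(wp); tot_n <- sum(wn)
    cp <- col_cumsum(matrix(wp[ord], n, d))[-n, , drop = FALSE]
    cn <- col_cumsum(matrix(wn[ord], n, d))[-n, , drop = FALSE]
    err_a <- cp + (tot_n - cn)                     # left -> 0, right -> 1
    err <- pmin(err_a, 1 - err_a)
    err[!valid] <- Inf
    best <- which.min(err)
    eps <- err[best]
    if (!is.finite(eps) || eps >= 0.5) break
    rounds <- m
    j <- (best - 1L) %/% (n - 1L) + 1L
    t <- (best - 1L) %% (n - 1L) + 1L
    thr <- (xs[t, j] + xs[t + 1L, j]) / 2
    left_is_neg <- err_a[best] <= 1 - err_a[best]
    pred <- if (left_is_neg) as.integer(x[, j] > thr) else as.integer(x[, j] <= thr)
    alpha <- log((1 - max(eps, 1e-12)) / max(eps, 1e-12))

    wl_p <- cp[t, j]; wl_n <- cn[t, j]
    wl <- wl_p + wl_n; wr <- 1 - wl
    gain <- 2 * tot_p * tot_n
    if (wl > 0) gain <- gain - 2 * wl_p * wl_n / wl
    if (wr > 0) gain <- gain - 2 * (tot_p - wl_p) * (tot_n - wl_n) / wr
    imp[j] <- imp[j] + alpha * gain

    miss <- pred != labels
    if (eps <= 0 || !any(miss)) break              # perfect stump: done
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  scores <- if (sum(imp) > 0) imp / sum(imp) else imp
  structure(
    list(names = colnames(x), scores = scores,
         ranking = order(-scores, seq_len(d)),
         n_estimators = as.integer(n_estimators), n_rounds = rounds,
         seed = as.integer(seed)),
    class = "adaboost_ranker"
  )
}

#' @export
print.adaboost_ranker <- function(x, ...) {
  cat(sprintf("<adaboost_ranker> %d features, %d/%d boosting rounds\n",
              length(x$scores), x$n_rounds, x$n_estimators))
  top <- utils::head(x$ranking, 5L)
  cat("top features:",
      paste(sprintf("%s (%.3f)", x$names[top] %||% top, x$scores[top]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Keep the top-n ranked features
#'
#' @param x Feature matrix whose columns match `model$names` in order.
#' @param model An [fit_adaboost_ranker()] model.
#' @param n Number of features to keep (`n <= ncol(x)`).
#'
#' @return `x` restricted to the top-n columns, in rank order. The top-m set
#'   is always a subset of the top-n set for m <= n.
#' @export
select_top <- function(x, model, n) {
  stopifnot(inherits(model, "adaboost_ranker"), is.matrix(x))
  if (!identical(colnames(x), model$names)) {
    stop("columns of `x` do not match the ranker's feature names", call. = FALSE)
  }
  if (n < 1L || n > ncol(x)) {
    stop("`n` must be between 1 and the number of features", call. = FALSE)
  }
  x[, model$ranking[seq_len(n)], drop = FALSE]
}

#' Serialise a ranked feature list
#'
#' Writes `(rank, feature, score)` rows as TSV; fit metadata travels in a
#' `# key=value` comment header.
#'
#' @param model An [fit_adaboost_ranker()] model.
#' @param path Output path.
#' @export
write_selection_tsv <- function(model, path) {
  stopifnot(inherits(model, "adaboost_ranker"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_estimators=%d n_rounds=%d seed=%d",
                     model$n_estimators, model$n_rounds, model$seed), con)
  utils::write.table(
    data.frame(rank = seq_along(model$ranking),
               feature = model$names[model$ranking] %||% model$ranking,
               score = model$scores[model$ranking]),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
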