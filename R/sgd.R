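# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Train a linear model by stochastic gradient descent
#'
#' Fits the linear score `h(theta) = theta_0 + sum_i theta_i x_i` by
#' per-sample least-mean-squares updates: for each visited row,
#' `theta <- theta - alpha * (h(x) - y) * x` (with `x_0 = 1` carrying the
#' bias). Weights start from a seeded uniform(-0.01, 0.01) draw and rows are
#' visited in a freshly seeded shuffled order each epoch, so the fit is
#' deterministic given `(x, alpha, epochs, seed)`. The learning rate is
#' constant. Columns are z-scored with training statistics by default, since
#' raw k-mer and descriptor blocks live on different scales; statistics are
#' stored in the model and re-applied at prediction time.
#'
#' A hinge-loss variant (`loss = "hinge"`, perceptron-style subgradient on
#' labels recoded to -1/+1) is available; the least-mean-squares default is
#' the reference behaviour.
#'
#' @param x Numeric feature matrix, all values finite.
#' @param y Targets in `[0, 1]`; classification uses 0/1 labels, but any
#'   values in the unit interval are accepted (the LMS update is a
#'   regression rule).
#' @param alpha Learning rate, > 0 (default 0.01).
#' @param lambda L2 (ridge) shrinkage applied per update to every weight
#'   except the bias (default 0 = plain least-mean-squares). A small
#'   positive value controls variance when the feature count approaches the
#'   sample count.
#' @param epochs Full passes over the data, >= 1 (default 1000).
#' @param seed RNG seed for initialisation and per-epoch shuffling.
#' @param threshold Decision threshold on the linear score (default 0.5);
#'   scores at or above it classify positive.
#' @param standardize Z-score columns with training statistics (default
#'   `TRUE`; constant columns get scale 1).
#' @param loss `"lms"` (default) or `"hinge"`.
#' @param track_loss Record the epoch-wise mean squared error
#'   `mean((h - y)^2) / 2` in the returned model (default `FALSE`).
#'
#' @return Object of class `sgd_model`: weights `theta` (bias first), the
#'   hyperparameters, the standardisation statistics and, if requested, the
#'   per-epoch `loss` trace.
#' @export
train_sgd <- function(x, y, alpha = 0.01, lambda = 0, epochs = 1000L,
                      seed = 1L, threshold = 0.5, standardize = TRUE,
                      loss = c("lms", "hinge"), track_loss = FALSE) {
  loss <- match.arg(loss)
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a positive number", call. = FALSE)
  }
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0) {
    stop("`lambda` must be a non-negative number", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  if (length(y) != nrow(x) || !all(is.finite(y)) || any(y < 0 | y > 1)) {
    stop("targets must be finite values in [0, 1] (0/1 labels for classification)",
         call. = FALSE)
  }
  n <- nrow(x); d <- ncol(x)
  center <- rep(0, d); scale <- rep(1, d)
  if (standardize) {
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    x <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  }
  xt <- t(cbind(1, x))
  dimnames(xt) <- NULL
  ys <- if (loss == "hinge") 2 * y - 1 else y
  fit <- with_seed(seed, {
    th0 <- stats::runif(d + 1L, -0.01, 0.01)
    orders <- vapply(seq_len(epochs), function(ep) sample.int(n), integer(n))
    sgd_loop(xt, ys, th0, orders, alpha, lambda,
             if (loss == "lms") 0L else 1L, track_loss)
  })
  theta <- fit$theta
  loss_trace <- if (track_loss) fit$trace else NULL
  names(theta) <- c("(bias)", colnames(x) %||% paste0("x", seq_len(d)))
  structure(
    list(theta = theta, alpha = alpha, lambda = lambda,
         epochs = as.integer(epochs),
         seed = as.integer(seed), threshold = threshold,
         standardize = standardize, center = center, scale = scale,
         loss = loss, feature_names = colnames(x),
         loss_trace = loss_trace),
    class = "sgd_model"
  )
}

#' @export
print.sgd_model <- function(x, ...) {
  cat(sprintf("<sgd_model> %d features + bias, loss = %s, alpha = %g, epochs = %d, seed = %d\n",
              length(x$theta) - 1L, x$loss, x$alpha, x$epochs, x$seed))
  invisible(x)
}

check_model_columns <- function(model, x) {
  if (ncol(x) != length(model$theta) - 1L) {
    stop(sprintf("model expects %d features, got %d",
                 length(model$theta) - 1L, ncol(x)), call. = FALSE)
  }
  if (!is.null(model$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), model$feature_names)) {
    missing <- setdiff(model$feature_names, colnames(x))
    extra <- setdiff(colnames(x), model$feature_names)
    stop("feature columns do not match the model",
         if (length(missing)) paste0("; missing: ", paste(utils::head(missing, 5), collapse = ",")),
         if (length(extra)) paste0("; extra: ", paste(utils::head(extra, 5), collapse = ",")),
         "; (or mis-ordered)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Linear decision value
#'
#' Computes `theta_0 + sum_i theta_i x_i` for each row, after applying the
#' model's stored standardisation.
#'
#' @param model An [train_sgd()] model.
#' @param x Numeric matrix (or single row vector) matching the model's
#'   feature columns.
#' @return Numeric vector of scores, one per row.
#' @export
decision_value <- function(model, x) {
  stopifnot(inherits(model, "sgd_model"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  check_model_columns(model, x)
  if (model$standardize) {
    x <- sweep(sweep(x, 2L, model$center, "-"), 2L, model$scale, "/")
  }
  drop(model$theta[1L] + x %*% model$theta[-1L])
}

#' Predict class labels
#'
#' @param object An [train_sgd()] model.
#' @param x Feature matrix matching the training columns.
#' @param type `"class"` for 0/1 labels (score >= threshold classifies
#'   positive, ties included) or `"decision"` for raw scores.
#' @param ... Unused.
#' @return Integer 0/1 vector or numeric score vector.
#' @export
predict.sgd_model <- function(object, x, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  dv <- decision_value(object, x)
  if (type == "decision") dv else as.integer(dv >= object$threshold)
}

#' Serialise / restore an SGD model as JSON
#'
#' The JSON carries the weights, hyperparameters, threshold and
#' standardisation statistics; a restored model reproduces decision values
#' to double precision (JSON number serialisation is not bitwise lossless).
#'
#' @param model An [train_sgd()] model.
#' @param path File path.
#' @export
write_sgd_model <- function(model, path) {
  stopifnot(inherits(model, "sgd_model"))
  payload <- model[c("theta", "alpha", "lambda", "epochs", "seed", "threshold",
                     "standardize", "center", "scale", "loss", "feature_names")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sgd_model
#' @export
read_sgd_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  theta <- unlist(p$theta)
  m <- list(theta = theta, alpha = p$alpha, lambda = p$lambda %||% 0,
            epochs = as.integer(p$epochs),
            seed = as.integer(p$seed), threshold = p$threshold,
            standardize = isTRUE(p$standardize),
            center = as.numeric(p$center), scale = as.numeric(p$scale),
            loss = p$loss,
            feature_names = if (length(p$feature_names)) as.character(p$feature_names),
            loss_trace = NULL)
  class(m) <- "sgd_model"
  m
}
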