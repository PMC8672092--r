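#' Confusion counts
#'
#' Tp, Fn, Fp, Tn with the positive class = phage virion protein = label 1.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return Object of class `confusion_counts`: list of integers `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("`y_true` and `y_pred` must be equal-length, non-empty", call. = FALSE)
  }
  if (!all(y_true %in% c(0L, 1L)) || !all(y_pred %in% c(0L, 1L))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(tp = sum(y_true == 1L & y_pred == 1L),
                 fn = sum(y_true == 1L & y_pred == 0L),
                 fp = sum(y_true == 0L & y_pred == 1L),
                 tn = sum(y_true == 0L & y_pred == 0L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> Tp=%d Fn=%d Fp=%d Tn=%d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity, accuracy, Matthews correlation
#'
#' Sn = Tp/(Tp+Fn), Sp = Tn/(Tn+Fp), ACC = (Tp+Tn)/n, and
#' MCC = (Tp*Tn - Fp*Fn) / sqrt((Tp+Fn)(Tn+Fn)(Tp+Fp)(Tn+Fp)). When the MCC
#' denominator is zero (a degenerate truth or prediction margin) MCC is 0 by
#' convention; Sn or Sp is `NA` when its class is absent from the truth.
#'
#' @param counts A [confusion_counts()] object (or list with tp/fn/fp/tn).
#' @return List of class `pvp_metrics` with `sn`, `sp`, `acc`, `mcc` and the
#'   counts.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fn <- as.numeric(counts$fn)
  fp <- as.numeric(counts$fp); tn <- as.numeric(counts$tn)
  n <- tp + fn + fp + tn
  if (n < 1) stop("all counts are zero", call. = FALSE)
  den <- sqrt((tp + fn) * (tn + fn) * (tp + fp) * (tn + fp))
  structure(
    list(sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         acc = (tp + tn) / n,
         mcc = if (den > 0) (tp * tn - fp * fn) / den else 0,
         counts = counts),
    class = "pvp_metrics"
  )
}

#' @export
print.pvp_metrics <- function(x, ...) {
  cat(sprintf("<pvp_metrics> Sn=%.4f Sp=%.4f ACC=%.4f MCC=%.4f\n",
              x$sn, x$sp, x$acc, x$mcc))
  invisible(x)
}

# stratified fold labels: within each class, seeded shuffle then round-robin
kfold_assign <- function(labels, folds, seed) {
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab < folds)) {
    stop(sprintf("each class needs >= %d members for %d-fold stratification",
                 folds, folds), call. = FALSE)
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified holdout split
#'
#' Draws a seeded, class-stratified split; per class, the training share is
#' `round(fraction * n_class)`. Train and test indices partition the input.
#'
#' @param labels 0/1 vector.
#' @param fraction Training fraction, strictly between 0 and 1 (default 0.8).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
holdout_split <- function(labels, fraction = 0.8, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("`fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  train <- integer(0)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      train <- c(train, sample(idx, round(fraction * length(idx))))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Stratified k-fold cross-validation of the pipeline
#'
#' Encodes the sequences once (encoding uses no labels), then, per fold,
#' fits the feature ranker (unless `selection_scope = "full"`), the
#' standardisation statistics and the SGD model on the training folds only
#' and predicts the held-out fold. Pooled confusion counts over all folds
#' give the primary (micro) metrics; the unweighted mean of per-fold metrics
#' is reported as the macro view.
#'
#' @param seqs Named character vector of valid sequences.
#' @param labels 0/1 vector aligned to `seqs`.
#' @param config A [pvp_config()].
#' @param folds Number of folds (default 10).
#' @param seed Seed for the stratified fold assignment.
#'
#' @return Object of class `pvp_cv`: pooled `metrics`, `macro` (mean fold
#'   Sn/Sp/ACC/MCC), `per_fold` data.frame, `counts`, the fold `assignment`
#'   and the echoed `config`.
#' @export
kfold_cv <- function(seqs, labels, config = pvp_config(), folds = 10L, seed = 1L) {
  stopifnot(inherits(config, "pvp_config"))
  labels <- as.integer(labels)
  assign <- kfold_assign(labels, folds, seed)
  blocks <- encode_blocks(seqs, config)
  full_ranker <- NULL
  if (config$selection_scope == "full" && config$n_select > 0L &&
      config$n_select < ncol(blocks$knc)) {
    full_ranker <- fit_adaboost_ranker(blocks$knc, labels,
                                       n_estimators = config$n_estimators,
                                       seed = config$selection_seed)
  }
  y_pred <- integer(length(labels))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- which(assign == f)
    train <- which(assign != f)
    fit <- fit_on_blocks(blocks, labels, config, rows = train,
                         ranker = full_ranker)
    y_pred[test] <- predict_on_blocks(fit, blocks, config, test)
    m <- classification_metrics(confusion_counts(labels[test], y_pred[test]))
    per_fold[[f]] <- data.frame(fold = f, n = length(test),
                                sn = m$sn, sp = m$sp, acc = m$acc, mcc = m$mcc)
  }
  per_fold <- do.call(rbind, per_fold)
  counts <- confusion_counts(labels, y_pred)
  structure(
    list(metrics = classification_metrics(counts),
         macro = colMeans(per_fold[, c("sn", "sp", "acc", "mcc")], na.rm = TRUE),
         per_fold = per_fold, counts = counts, assignment = assign,
         folds = as.integer(folds), seed = as.integer(seed), config = config),
    class = "pvp_cv"
  )
}

#' @export
print.pvp_cv <- function(x, ...) {
  cat(sprintf("<pvp_cv> %d-fold, pooled: Sn=%.4f Sp=%.4f ACC=%.4f MCC=%.4f\n",
              x$folds, x$metrics$sn, x$metrics$sp, x$metrics$acc, x$metrics$mcc))
  cat(sprintf("          macro:  Sn=%.4f Sp=%.4f ACC=%.4f MCC=%.4f\n",
              x$macro["sn"], x$macro["sp"], x$macro["acc"], x$macro["mcc"]))
  invisible(x)
}

#' Holdout evaluation of the pipeline
#'
#' Stratified seeded split, fit on the training share, metrics on the rest.
#'
#' @inheritParams kfold_cv
#' @param fraction Training fraction (default 0.8).
#'
#' @return List of class `pvp_holdout`: `metrics`, `counts`, `split` (the
#'   index lists), `model` (the fitted [fit_pvp()] model on the training
#'   share) and `config`.
#' @export
holdout_eval <- function(seqs, labels, config = pvp_config(), fraction = 0.8,
                         seed = 1L) {
  labels <- as.integer(labels)
  split <- holdout_split(labels, fraction, seed)
  blocks <- encode_blocks(seqs, config)
  fit <- fit_on_blocks(blocks, labels, config, rows = split$train)
  y_pred <- predict_on_blocks(fit, blocks, config, split$test)
  counts <- confusion_counts(labels[split$test], y_pred)
  structure(
    list(metrics = classification_metrics(counts), counts = counts,
         split = split,
         model = structure(c(fit, list(config = config,
                                       n_train = length(split$train))),
                           class = "pvp_model"),
         config = config, seed = as.integer(seed), fraction = fraction),
    class = "pvp_holdout"
  )
}

#' @export
print.pvp_holdout <- function(x, ...) {
  cat(sprintf("<pvp_holdout> train %d / test %d: Sn=%.4f Sp=%.4f ACC=%.4f MCC=%.4f\n",
              length(x$split$train), length(x$split$test),
              x$metrics$sn, x$metrics$sp, x$metrics$acc, x$metrics$mcc))
  invisible(x)
}
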