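#' Pipeline configuration
#'
#' Collects every tunable of the fused k-mer + 188D prediction pipeline in
#' one validated list. Defaults follow the reference configuration: k = 3
#' with the top 260 boosted-stump-selected k-mer features fused with the 188
#' descriptor columns (448 total); k = 2 keeps 147 (335 fused) and k = 1
#' keeps all 20 (208 fused). The per-k selection counts are chosen so the
#' fused dimensions land on 208/335/448.
#'
#' @param k ktuple for the k-mer composition encoder (1..5).
#' @param use_188d Fuse the 188-dimensional descriptor block (default TRUE;
#'   protein only).
#' @param n_select Number of k-mer features retained by the AdaBoost ranker;
#'   `NULL` picks the default for `k` (0 = keep all, no ranking), 0 disables
#'   selection.
#' @param n_estimators Boosting rounds for the ranker (default 100).
#' @param selection_seed Metadata seed recorded with the ranker.
#' @param alpha,lambda,epochs,sgd_seed,threshold,standardize,loss Passed to
#'   [train_sgd()]. `alpha = NULL` (the default) resolves at fit time to
#'   `min(0.01, 1 / (p + 1))` for p fused features, which keeps the
#'   constant-rate least-mean-squares update inside its stability region
#'   (roughly `alpha < 2 / p` for z-scored columns) at every fused
#'   dimension. The default ridge term `lambda = 0.3` (on the z-scored
#'   feature scale) controls estimator variance in the regime this pipeline
#'   lives in, where the fused feature count is of the same order as the
#'   sample count; `lambda = 0` recovers the plain least-mean-squares
#'   update.
#' @param selection_scope `"train"` (default) fits the feature ranker inside
#'   each cross-validation training split only, keeping evaluation
#'   leakage-free; `"full"` fits it once on the whole matrix before
#'   splitting, mimicking protocols that select features up front.
#' @param alphabet Sequence alphabet (coerced by [alphabet()]).
#'
#' @return A validated list of class `pvp_config`.
#' @export
pvp_config <- function(k = 3L, use_188d = TRUE, n_select = NULL,
                       n_estimators = 100L, selection_seed = 1L,
                       alpha = NULL, lambda = 0.3, epochs = 1000L,
                       sgd_seed = 1L,
                       threshold = 0.5, standardize = TRUE,
                       loss = c("lms", "hinge"),
                       selection_scope = c("train", "full"),
                       alphabet = "protein") {
  loss <- match.arg(loss)
  selection_scope <- match.arg(selection_scope)
  alphabet <- as_alphabet(alphabet)
  k <- as.integer(k)
  if (is.null(n_select)) {
    n_select <- if (k <= 1L) 0L else if (k == 2L) 147L else 260L
  }
  n_select <- as.integer(n_select)
  if (use_188d && alphabet$kind != "PROTEIN") {
    stop("the 188D descriptor block needs a protein alphabet", call. = FALSE)
  }
  if (n_select < 0L) stop("`n_select` must be >= 0", call. = FALSE)
  if (!is.null(alpha) && (!is.numeric(alpha) || length(alpha) != 1L ||
                          !is.finite(alpha) || alpha <= 0)) {
    stop("`alpha` must be a positive number or NULL for the automatic rate",
         call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda < 0) {
    stop("`lambda` must be a non-negative number", call. = FALSE)
  }
  structure(
    list(k = k, use_188d = use_188d, n_select = n_select,
         n_estimators = as.integer(n_estimators),
         selection_seed = as.integer(selection_seed),
         alpha = alpha, lambda = lambda, epochs = as.integer(epochs),
         sgd_seed = as.integer(sgd_seed), threshold = threshold,
         standardize = standardize, loss = loss,
         selection_scope = selection_scope, alphabet = alphabet),
    class = "pvp_config"
  )
}

#' @export
print.pvp_config <- function(x, ...) {
  cat(sprintf(
    "<pvp_config> %s k=%d (+188D: %s), n_select=%d, boosting=%d, sgd alpha=%s epochs=%d, scope=%s\n",
    x$alphabet$kind, x$k, x$use_188d, x$n_select, x$n_estimators,
    if (is.null(x$alpha)) "auto" else format(x$alpha), x$epochs,
    x$selection_scope))
  invisible(x)
}

# encode both feature blocks once; selection/fusion happen per training split
encode_blocks <- function(seqs, config) {
  space <- kmer_feature_names(config$alphabet, config$k)
  knc <- encode_knc(seqs, space)
  colnames(knc) <- paste0("knc_", colnames(knc))
  d188 <- NULL
  if (config$use_188d) d188 <- encode_188d_batch(seqs)
  list(knc = knc, d188 = d188)
}

fuse_blocks <- function(knc, d188, selected_knc) {
  sel <- if (is.null(selected_knc)) knc else knc[, selected_knc, drop = FALSE]
  if (is.null(d188)) sel else combine_features(sel, d188)
}

fit_on_blocks <- function(blocks, labels, config, rows = seq_along(labels),
                          ranker = NULL) {
  knc <- blocks$knc[rows, , drop = FALSE]
  d188 <- if (!is.null(blocks$d188)) blocks$d188[rows, , drop = FALSE]
  selected_knc <- NULL
  if (config$n_select > 0L && config$n_select < ncol(knc)) {
    if (is.null(ranker)) {
      ranker <- fit_adaboost_ranker(knc, labels[rows],
                                    n_estimators = config$n_estimators,
                                    seed = config$selection_seed)
    }
    selected_knc <- colnames(select_top(knc, ranker, config$n_select))
  }
  fused <- fuse_blocks(knc, d188, selected_knc)
  alpha <- config$alpha %||% min(0.01, 1 / (ncol(fused) + 1))
  sgd <- train_sgd(fused, labels[rows], alpha = alpha, lambda = config$lambda,
                   epochs = config$epochs, seed = config$sgd_seed,
                   threshold = config$threshold,
                   standardize = config$standardize, loss = config$loss)
  list(ranker = ranker, selected_knc = selected_knc, sgd = sgd,
       feature_names = colnames(fused))
}

predict_on_blocks <- function(fit, blocks, config, rows, type = "class") {
  knc <- blocks$knc[rows, , drop = FALSE]
  d188 <- if (!is.null(blocks$d188)) blocks$d188[rows, , drop = FALSE]
  fused <- fuse_blocks(knc, d188, fit$selected_knc)
  predict(fit$sgd, fused, type = type)
}

#' Fit the full prediction pipeline
#'
#' Encodes the sequences (k-mer composition and, for proteins, the 188D
#' block), ranks the k-mer features with boosted stumps and keeps the
#' configured top-n, fuses the blocks, and trains the SGD linear model.
#'
#' @param seqs Named character vector of valid sequences.
#' @param labels 0/1 vector aligned to `seqs` (1 = phage virion protein).
#' @param config A [pvp_config()].
#'
#' @return Object of class `pvp_model` holding the configuration, the
#'   feature ranker (if any), the trained [train_sgd()] model, and the fused
#'   feature-name vector.
#' @export
fit_pvp <- function(seqs, labels, config = pvp_config()) {
  stopifnot(inherits(config, "pvp_config"))
  labels <- as.integer(labels)
  if (length(labels) != length(seqs) || !all(labels %in% c(0L, 1L))) {
    stop("`labels` must be a 0/1 vector aligned to `seqs`", call. = FALSE)
  }
  blocks <- encode_blocks(seqs, config)
  fit <- fit_on_blocks(blocks, labels, config)
  structure(c(fit, list(config = config, n_train = length(seqs))),
            class = "pvp_model")
}

#' @export
print.pvp_model <- function(x, ...) {
  cat(sprintf("<pvp_model> %d fused features (k=%d%s), trained on %d sequences\n",
              length(x$feature_names), x$config$k,
              if (x$config$use_188d) " + 188D" else "", x$n_train))
  invisible(x)
}

#' Predict phage virion proteins for new sequences
#'
#' @param object A [fit_pvp()] model.
#' @param seqs Named character vector of sequences, valid over the model's
#'   alphabet.
#' @param type `"class"`, `"decision"`, or `"table"` (data.frame of id,
#'   decision value and label).
#' @param ... Unused.
#' @export
predict.pvp_model <- function(object, seqs, type = c("class", "decision", "table"), ...) {
  type <- match.arg(type)
  blocks <- encode_blocks(seqs, object$config)
  fit <- object[c("selected_knc", "sgd")]
  dv <- predict_on_blocks(fit, blocks, object$config, seq_along(seqs),
                          type = "decision")
  lab <- as.integer(dv >= object$sgd$threshold)
  switch(type,
         class = lab,
         decision = dv,
         table = data.frame(id = names(seqs) %||% as.character(seq_along(seqs)),
                            decision = dv, label = lab,
                            stringsAsFactors = FALSE))
}
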