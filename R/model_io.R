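#' Serialise / restore a fitted pipeline model as JSON
#'
#' The JSON records the resolved configuration (including the encoder's
#' alphabet and k, so a restored model refuses incompatible inputs), the
#' retained k-mer feature names in rank order, and the SGD weights with
#' their standardisation statistics. Round-tripping reproduces decision
#' values to double precision.
#'
#' @param model A [fit_pvp()] model.
#' @param path File path.
#' @export
write_pvp_model <- function(model, path) {
  stopifnot(inherits(model, "pvp_model"))
  cfg <- model$config
  payload <- list(
    config = list(k = cfg$k, use_188d = cfg$use_188d, n_select = cfg$n_select,
                  n_estimators = cfg$n_estimators,
                  selection_seed = cfg$selection_seed,
                  alpha = cfg$alpha %||% "auto", lambda = cfg$lambda,
                  epochs = cfg$epochs, sgd_seed = cfg$sgd_seed,
                  threshold = cfg$threshold, standardize = cfg$standardize,
                  loss = cfg$loss, selection_scope = cfg$selection_scope,
                  alphabet = cfg$alphabet$kind),
    selected_knc = model$selected_knc,
    n_train = model$n_train,
    sgd = model$sgd[c("theta", "alpha", "lambda", "epochs", "seed", "threshold",
                      "standardize", "center", "scale", "loss",
                      "feature_names")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pvp_model
#' @export
read_pvp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$config$alpha, "auto")) p$config$alpha <- NULL
  cfg <- do.call(pvp_config, c(p$config[setdiff(names(p$config), "alphabet")],
                               list(alphabet = tolower(p$config$alphabet))))
  sgd <- list(theta = unlist(p$sgd$theta), alpha = p$sgd$alpha,
              lambda = p$sgd$lambda %||% 0,
              epochs = as.integer(p$sgd$epochs), seed = as.integer(p$sgd$seed),
              threshold = p$sgd$threshold,
              standardize = isTRUE(p$sgd$standardize),
              center = as.numeric(p$sgd$center),
              scale = as.numeric(p$sgd$scale), loss = p$sgd$loss,
              feature_names = if (length(p$sgd$feature_names)) {
                as.character(p$sgd$feature_names)
              }, loss_trace = NULL)
  class(sgd) <- "sgd_model"
  structure(
    list(ranker = NULL,
         selected_knc = if (length(p$selected_knc)) as.character(p$selected_knc),
         sgd = sgd, feature_names = sgd$feature_names,
         config = cfg, n_train = as.integer(p$n_train)),
    class = "pvp_model"
  )
}
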