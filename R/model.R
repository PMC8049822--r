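#' Train the final SVM on a full feature matrix
#'
#' Fits the RBF C-SVC on all rows of `features` (optionally restricted to
#' `selected` feature names, e.g. an IFS prefix) and wraps the fitted dual
#' solution with its encoding provenance — scheme notation, N, feature
#' names — so later predictions fail loudly on mismatched encodings.
#'
#' @param features A `raac_features` matrix.
#' @param config A `raac_svm_config`.
#' @param selected Optional character vector of feature names to train on,
#'   in ranking order; defaults to all columns.
#' @param seed Seed recorded in the model (training itself is
#'   deterministic).
#' @return An object of class `raac_model`.
#' @export
train_final <- function(features, config, selected = NULL, seed = 1L) {
  stopifnot(inherits(features, "raac_features"),
            inherits(config, "raac_svm_config"))
  if (!is.null(selected)) features <- subset_features(features, selected)
  config <- resolve_config(config, features$x)
  d2 <- d2_matrix(features$x)
  fit <- svm_fit_d2(d2, features$labels, config)
  sv <- which(fit$alpha > 0)
  structure(
    list(
      sv_x = features$x[sv, , drop = FALSE],
      sv_coef = fit$alpha[sv] * fit$ysign[sv],
      rho = fit$rho,
      config = config,
      scheme_notation = format_scheme(features$scheme),
      scheme_type = features$scheme$type_id,
      scheme_size = features$scheme$size,
      N = features$N,
      feature_names = features$feature_names,
      n_train = nrow(features$x),
      seed = as.integer(seed)
    ),
    class = "raac_model"
  )
}

#' @export
print.raac_model <- function(x, ...) {
  cat(sprintf(
    "RBF SVM model: %d support vectors / %d training samples\n  scheme type %d size %d, N = %d, %d features; C = 2^%g, gamma = 2^%g\n",
    nrow(x$sv_x), x$n_train, x$scheme_type, x$scheme_size, x$N,
    length(x$feature_names), log2(x$config$C), log2(x$config$gamma)))
  invisible(x)
}

#' Predict classes and decision scores for new samples
#'
#' `newdata` must be a `raac_features` matrix built with the same scheme and
#' N as the model (its columns are subset to the model's selected features);
#' a mismatch is an error, not a silent re-encoding.
#'
#' @param object A `raac_model`.
#' @param newdata A `raac_features` matrix.
#' @param ... Unused.
#' @return Data.frame with `id`, `score` (decision value) and `class`
#'   (1 if score > 0 else 0).
#' @export
predict.raac_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "raac_features"))
  if (format_scheme(newdata$scheme) != object$scheme_notation ||
      newdata$N != object$N) {
    stop(sprintf(
      "encoding mismatch: model expects scheme '%s' with N = %d, matrix was built with scheme '%s', N = %d",
      object$scheme_notation, object$N,
      format_scheme(newdata$scheme), newdata$N), call. = FALSE)
  }
  newdata <- subset_features(newdata, object$feature_names)
  d2 <- d2_cross(newdata$x, object$sv_x)
  score <- as.numeric(rbf_kernel(d2, object$config$gamma) %*% object$sv_coef) -
    object$rho
  data.frame(id = newdata$sample_ids, score = score,
             class = as.integer(score > 0), stringsAsFactors = FALSE)
}

#' Serialize a trained model to a single JSON file
#'
#' Numbers are written with 17 significant digits so a reloaded model gives
#' predictions identical to the original.
#'
#' @param model A `raac_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "raac_model"))
  payload <- list(
    format = "raackit-model-1",
    scheme_notation = model$scheme_notation,
    scheme_type = model$scheme_type,
    scheme_size = model$scheme_size,
    N = model$N,
    feature_names = model$feature_names,
    C = model$config$C,
    gamma = model$config$gamma,
    rho = model$rho,
    sv_coef = model$sv_coef,
    sv_x = model$sv_x,
    n_train = model$n_train,
    seed = model$seed
  )
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  if (is.null(p$format) || p$format != "raackit-model-1") {
    stop("not a raackit model file: ", path, call. = FALSE)
  }
  sv_x <- p$sv_x
  if (!is.matrix(sv_x)) {
    sv_x <- matrix(sv_x, ncol = length(p$feature_names), byrow = TRUE)
  }
  colnames(sv_x) <- p$feature_names
  structure(
    list(sv_x = sv_x, sv_coef = as.numeric(p$sv_coef), rho = p$rho,
         config = svm_config(p$C, p$gamma),
         scheme_notation = p$scheme_notation,
         scheme_type = as.integer(p$scheme_type),
         scheme_size = as.integer(p$scheme_size),
         N = as.integer(p$N), feature_names = p$feature_names,
         n_train = as.integer(p$n_train), seed = as.integer(p$seed)),
    class = "raac_model"
  )
}
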