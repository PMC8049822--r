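#' Rank features by two-group one-way ANOVA F-score
#'
#' For each feature, F is the between-group mean square over the
#' within-group mean square (degrees of freedom 1 and n - 2). Features with
#' zero within-group variance but distinct group means score `Inf` and rank
#' first; features constant everywhere score 0 and rank last. Ties keep the
#' original column order.
#'
#' @param features A `raac_features` matrix with both classes present
#'   (at least 2 samples each).
#' @return An object of class `raac_ranking`: data.frame `entries` with
#'   columns `feature`, `F`, `column` (original index), sorted by descending
#'   F; plus `n_pos`, `n_neg`.
#' @export
anova_f_scores <- function(features) {
  stopifnot(inherits(features, "raac_features"))
  x <- features$x
  y <- features$labels
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) {
    stop("degenerate groups: each class needs at least 2 samples", call. = FALSE)
  }
  f <- anova_f_vector(x, y)
  ord <- order(-f, seq_along(f))
  entries <- data.frame(feature = colnames(x)[ord], F = f[ord],
                        column = ord, stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  structure(list(entries = entries, n_pos = n1, n_neg = n0),
            class = "raac_ranking")
}

# Vectorized over columns. 0/0 (constant feature) -> 0; x/0 -> Inf.
anova_f_vector <- function(x, y) {
  pos <- y == 1L
  n1 <- sum(pos); n0 <- sum(!pos); n <- n1 + n0
  m1 <- colMeans(x[pos, , drop = FALSE])
  m0 <- colMeans(x[!pos, , drop = FALSE])
  grand <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - grand)^2 + n0 * (m0 - grand)^2
  ssw <- colSums(sweep(x[pos, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!pos, , drop = FALSE], 2, m0)^2)
  msb <- ssb / 1
  msw <- ssw / (n - 2)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  unname(f)
}

#' @export
print.raac_ranking <- function(x, ...) {
  cat(sprintf("ANOVA F ranking of %d features (%d pos / %d neg); top 5:\n",
              nrow(x$entries), x$n_pos, x$n_neg))
  print(utils::head(x$entries, 5))
  invisible(x)
}

#' Incremental feature selection over an ANOVA ranking
#'
#' Evaluates cross-validated accuracy of the SVM on growing prefixes of the
#' ranked feature list (k = 1, 1 + step, ...). The optimal k attains the
#' maximum accuracy; ties go to the smallest k (fewer features, less
#' overfitting risk). Each prefix can be grid-searched (`grid` a list of
#' configs) or run at a fixed configuration (`grid` a single config), the
#' latter being much faster.
#'
#' @param features A `raac_features` matrix.
#' @param ranking A `raac_ranking` from [anova_f_scores()] on the same
#'   matrix.
#' @param grid A `raac_svm_config` or list of them.
#' @param folds,seed Cross-validation parameters, shared across all k.
#' @param step Prefix increment (default 1).
#' @param max_features Cap on the largest prefix (default: all features).
#' @return An object of class `raac_ifs`: data.frame `points` (`k`,
#'   `cv_accuracy`, `C`, `gamma`), `optimal_k`, `optimal_accuracy`.
#' @export
incremental_feature_selection <- function(features, ranking, grid,
                                          folds = 5L, seed = 1L,
                                          step = 1L, max_features = NULL) {
  stopifnot(inherits(features, "raac_features"),
            inherits(ranking, "raac_ranking"))
  if (!setequal(ranking$entries$feature, features$feature_names)) {
    stop("ranking does not match the feature matrix columns", call. = FALSE)
  }
  if (inherits(grid, "raac_svm_config")) grid <- list(grid)
  if (!length(grid)) stop("configuration error: empty grid", call. = FALSE)
  p_all <- nrow(ranking$entries)
  p_max <- if (is.null(max_features)) p_all else min(max_features, p_all)
  ks <- seq.int(1L, p_max, by = step)
  y <- features$labels
  fold_id <- make_folds(y, folds, seed)
  ord_cols <- ranking$entries$column

  # d2 over a prefix grows by one rank-1 term per added column, so the
  # squared-distance matrix is maintained incrementally across k.
  n <- nrow(features$x)
  d2 <- matrix(0, n, n)
  have <- 0L
  points <- vector("list", length(ks))
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    while (have < k) {
      have <- have + 1L
      col <- features$x[, ord_cols[have]]
      d2 <- d2 + outer(col, col, "-")^2
    }
    grid_k <- lapply(grid, resolve_config,
                     x = features$x[, ord_cols[seq_len(k)], drop = FALSE])
    score_list <- cv_scores_engine(NULL, y, grid_k, fold_id, d2 = d2)
    acc <- vapply(score_list, function(s) mean((s > 0) == (y == 1L)), 0)
    tab_ord <- order(-acc, vapply(grid_k, `[[`, 0, "C"),
                     vapply(grid_k, `[[`, 0, "gamma"))
    b <- tab_ord[1]
    points[[ki]] <- data.frame(k = k, cv_accuracy = acc[b],
                               C = grid_k[[b]]$C, gamma = grid_k[[b]]$gamma)
  }
  points <- do.call(rbind, points)
  best <- which(points$cv_accuracy == max(points$cv_accuracy))[1]
  structure(
    list(points = points, optimal_k = points$k[best],
         optimal_accuracy = points$cv_accuracy[best],
         features = ranking$entries$feature, folds = folds, seed = seed),
    class = "raac_ifs"
  )
}

#' @export
print.raac_ifs <- function(x, ...) {
  cat(sprintf("IFS curve over %d prefixes: optimal k = %d, accuracy %.4f\n",
              nrow(x$points), x$optimal_k, x$optimal_accuracy))
  invisible(x)
}

#' Write an IFS curve as two-column delimited text
#'
#' @param ifs A `raac_ifs` object.
#' @param path Output path.
#' @export
write_ifs_curve <- function(ifs, path) {
  stopifnot(inherits(ifs, "raac_ifs"))
  utils::write.table(ifs$points[, c("k", "cv_accuracy")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
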