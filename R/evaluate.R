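#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/(TP+FN+TN+FP). Both
#' classes must be represented: an empty class makes Sn or Sp undefined and
#' raises an error rather than silently returning 0.
#'
#' @param confusion Named list or vector with `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(Sn, Sp, Acc)`.
#' @examples
#' compute_metrics(c(TP = 3, FN = 1, TN = 4, FP = 2)) # 0.75 0.667 0.70
#' @export
compute_metrics <- function(confusion) {
  cf <- as.list(confusion)
  need <- c("TP", "TN", "FP", "FN")
  stopifnot(all(need %in% names(cf)))
  TP <- cf$TP; TN <- cf$TN; FP <- cf$FP; FN <- cf$FN
  stopifnot(all(c(TP, TN, FP, FN) >= 0))
  if (TP + FN == 0) {
    stop("undefined metric: no positive samples (TP + FN = 0)", call. = FALSE)
  }
  if (TN + FP == 0) {
    stop("undefined metric: no negative samples (TN + FP = 0)", call. = FALSE)
  }
  c(Sn = TP / (TP + FN), Sp = TN / (TN + FP),
    Acc = (TP + TN) / (TP + FN + TN + FP))
}

#' ROC curve and area under it
#'
#' Thresholds sweep the distinct decision values from high to low; each
#' threshold contributes a point (false positive rate, true positive rate),
#' anchored at (0, 0) and (1, 1). The area is the trapezoidal sum, which for
#' tied scores equals the rank statistic
#' \eqn{P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)}.
#'
#' @param scores Numeric decision values, larger = more positive.
#' @param labels Binary labels (1 = positive, 0 = negative).
#' @return List with `roc_points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined AUC: both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # collapse tied scores: cumulative counts at each distinct threshold
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y == 1L)[last_of_tie]
  cum_fp <- cumsum(y == 0L)[last_of_tie]
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  thr <- c(Inf, s[last_of_tie])
  auc <- sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

# Stratified fold assignment: within each class the (seed-shuffled) samples
# are dealt round-robin, so per-fold class counts differ from balance by at
# most one sample. Returns an integer fold id per sample.
make_folds <- function(labels, folds, seed) {
  stopifnot(folds >= 2)
  labels <- as.integer(labels)
  if (min(sum(labels == 1L), sum(labels == 0L)) < folds) {
    stop("stratification error: a class has fewer samples than folds",
         call. = FALSE)
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(1L, 0L)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

# Evaluate a set of configs over fixed folds on a fixed feature matrix,
# reusing the squared-distance matrix. Returns pooled out-of-fold scores
# per config. The shared engine behind cross_validate, grid_search and IFS.
cv_scores_engine <- function(x, y01, configs, fold_id, d2 = NULL) {
  if (is.null(d2)) d2 <- d2_matrix(x)
  folds <- max(fold_id)
  n <- length(y01)
  lapply(configs, function(cfg) {
    scores <- numeric(n)
    for (f in seq_len(folds)) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      fit <- svm_fit_d2(d2[tr, tr, drop = FALSE], y01[tr], cfg)
      scores[te] <- svm_decision_d2(fit, d2[te, tr, drop = FALSE])
    }
    scores
  })
}

pooled_confusion <- function(scores, y01) {
  pred <- as.integer(scores > 0)
  c(TP = sum(pred == 1L & y01 == 1L), TN = sum(pred == 0L & y01 == 0L),
    FP = sum(pred == 1L & y01 == 0L), FN = sum(pred == 0L & y01 == 1L))
}

#' Stratified k-fold cross-validation of an RBF SVM
#'
#' Folds are stratified by class with a seed-determined shuffle; the pooled
#' out-of-fold decision values (native SVM threshold 0) give one confusion
#' matrix, Sn/Sp/Acc, and the ROC/AUC. Identical seeds give identical
#' reports.
#'
#' @param features A `raac_features` matrix.
#' @param config A `raac_svm_config`.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold shuffle.
#' @return An object of class `raac_eval`: confusion counts, `Sn`, `Sp`,
#'   `Acc`, `roc_points`, `AUC`, `per_fold` accuracy table, pooled `scores`,
#'   `config`, `folds`, `seed`.
#' @export
cross_validate <- function(features, config, folds = 5L, seed = 1L) {
  stopifnot(inherits(features, "raac_features"),
            inherits(config, "raac_svm_config"))
  config <- resolve_config(config, features$x)
  y <- features$labels
  fold_id <- make_folds(y, folds, seed)
  scores <- cv_scores_engine(features$x, y, list(config), fold_id)[[1]]
  build_eval(scores, y, fold_id, config, folds, seed)
}

build_eval <- function(scores, y01, fold_id, config, folds, seed) {
  cf <- pooled_confusion(scores, y01)
  metrics <- compute_metrics(cf)
  roc <- roc_auc(scores, y01)
  per_fold <- do.call(rbind, lapply(seq_len(max(fold_id)), function(f) {
    te <- fold_id == f
    pf <- pooled_confusion(scores[te], y01[te])
    data.frame(fold = f, n = sum(te), TP = pf["TP"], TN = pf["TN"],
               FP = pf["FP"], FN = pf["FN"],
               Acc = (pf["TP"] + pf["TN"]) / sum(te), row.names = NULL)
  }))
  structure(
    list(confusion = cf, Sn = unname(metrics["Sn"]),
         Sp = unname(metrics["Sp"]), Acc = unname(metrics["Acc"]),
         roc_points = roc$roc_points, AUC = roc$auc, per_fold = per_fold,
         scores = scores, labels = y01, config = config,
         folds = folds, seed = seed),
    class = "raac_eval"
  )
}

#' @export
print.raac_eval <- function(x, ...) {
  cat(sprintf(
    "%d-fold cross-validation (seed %d): Acc %.4f, Sn %.4f, Sp %.4f, AUC %.4f\n",
    x$folds, x$seed, x$Acc, x$Sn, x$Sp, x$AUC))
  cat(sprintf("  confusion: TP %d  FN %d  TN %d  FP %d\n",
              x$confusion["TP"], x$confusion["FN"],
              x$confusion["TN"], x$confusion["FP"]))
  invisible(x)
}

#' Grid search for C and gamma by cross-validated accuracy
#'
#' Every configuration is evaluated on the same stratified folds; the one
#' maximizing pooled cross-validated accuracy wins, ties broken by smaller
#' C then smaller gamma.
#'
#' @inheritParams cross_validate
#' @param grid Non-empty list of `raac_svm_config`.
#' @return List with `best` (config), `accuracy`, and `table` (data.frame of
#'   C, gamma, accuracy for the whole grid).
#' @export
grid_search <- function(features, grid, folds = 5L, seed = 1L) {
  stopifnot(inherits(features, "raac_features"))
  if (!length(grid)) stop("configuration error: empty grid", call. = FALSE)
  if (inherits(grid, "raac_svm_config")) grid <- list(grid)
  grid <- lapply(grid, resolve_config, x = features$x)
  y <- features$labels
  fold_id <- make_folds(y, folds, seed)
  score_list <- cv_scores_engine(features$x, y, grid, fold_id)
  acc <- vapply(score_list, function(s) mean((s > 0) == (y == 1L)), 0)
  tab <- data.frame(C = vapply(grid, `[[`, 0, "C"),
                    gamma = vapply(grid, `[[`, 0, "gamma"),
                    accuracy = acc)
  ord <- order(-tab$accuracy, tab$C, tab$gamma)
  best_i <- ord[1]
  list(best = grid[[best_i]], accuracy = acc[best_i], table = tab)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}
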