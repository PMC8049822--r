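make_features <- function(x, labels) {
  colnames(x) <- paste0("F", seq_len(ncol(x)))
  structure(
    list(x = x, sample_ids = paste0("s", seq_len(nrow(x))),
         feature_names = colnames(x), labels = as.integer(labels),
         scheme = parse_cluster_string("CFILMVWY-ADEGHKNPQRST", 19L, 2L),
         N = 1L, excluded = character(0)),
    class = "raac_features"
  )
}

test_that("worked ANOVA cases: F = 8, constants 0, separators Inf", {
  fm <- make_features(cbind(c(0, 1, 2, 3),        # [0,1] vs [2,3] -> F = 8
                            c(5, 5, 5, 5),        # constant -> 0, last
                            c(1, 1, 2, 2)),       # zero within-var -> Inf, first
                      c(1, 1, 0, 0))
  rk <- anova_f_scores(fm)
  expect_equal(rk$entries$F[rk$entries$feature == "F1"], 8)
  expect_equal(rk$entries$feature, c("F3", "F1", "F2"))
  expect_equal(rk$entries$F, c(Inf, 8, 0))
  expect_equal(rk$n_pos, 2)
  expect_equal(rk$n_neg, 2)
})

test_that("a class with fewer than 2 samples is degenerate", {
  fm <- make_features(matrix(rnorm(8), 4), c(1, 0, 0, 0))
  expect_error(anova_f_scores(fm), "degenerate")
})

test_that("F-scores match the closed-form oracle on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    x <- matrix(rnorm(20 * 10), 20, 10)
    y <- rep(c(1L, 0L), c(8, 12))
    fm <- make_features(x, y)
    rk <- anova_f_scores(fm)
    want <- vapply(seq_len(ncol(x)),
                   function(j) oracle_anova_f(x[y == 1L, j], x[y == 0L, j]), 0)
    got <- rk$entries$F[order(rk$entries$column)]
    expect_equal(got, want, tolerance = 1e-9)
    # descending order with ties by original column
    expect_true(all(diff(rk$entries$F) <= 0))
  }
})

test_that("F is location-invariant and scale-invariant", {
  set.seed(9)
  x <- matrix(rnorm(30 * 5), 30, 5)
  y <- rep(c(1L, 0L), c(10, 20))
  f0 <- anova_f_scores(make_features(x, y))$entries
  f_shift <- anova_f_scores(make_features(x + 7, y))$entries
  f_scale <- anova_f_scores(make_features(x * -3.5, y))$entries
  expect_equal(f0$F, f_shift$F, tolerance = 1e-9)
  expect_equal(f0$F, f_scale$F, tolerance = 1e-9)
})

test_that("IFS finds a single perfect separator at k = 1", {
  fm <- separable_features(12, 12, p_noise = 3, seed = 5)
  rk <- anova_f_scores(fm)
  expect_equal(rk$entries$feature[1], "F1") # separator ranks first
  ifs <- incremental_feature_selection(fm, rk, grid = svm_config(8, 1),
                                       folds = 3, seed = 2)
  expect_equal(ifs$optimal_k, 1L)
  expect_equal(ifs$optimal_accuracy, 1.0)
  expect_equal(nrow(ifs$points), 4) # curve length = feature count at step 1
  expect_equal(ifs$points$k, 1:4)
})

test_that("a duplicated informative column adds no information", {
  fm <- separable_features(10, 10, p_noise = 0, seed = 3)
  fm$x <- cbind(fm$x, fm$x[, 1])
  colnames(fm$x) <- c("F1", "F1b")
  fm$feature_names <- colnames(fm$x)
  rk <- anova_f_scores(fm)
  ifs <- incremental_feature_selection(fm, rk, grid = svm_config(8, 1),
                                       folds = 2, seed = 4)
  expect_equal(ifs$points$cv_accuracy[2], ifs$points$cv_accuracy[1])
})

test_that("IFS is deterministic under a fixed seed and respects ties -> smallest k", {
  fm <- separable_features(10, 10, p_noise = 5, seed = 8)
  rk <- anova_f_scores(fm)
  a <- incremental_feature_selection(fm, rk, grid = svm_config(8, 1),
                                     folds = 3, seed = 7)
  b <- incremental_feature_selection(fm, rk, grid = svm_config(8, 1),
                                     folds = 3, seed = 7)
  expect_identical(a$points, b$points)
  # optimal_k is the first k attaining the max
  expect_equal(a$optimal_k,
               a$points$k[which(a$points$cv_accuracy == max(a$points$cv_accuracy))[1]])
  # and the optimum dominates the full-feature prefix
  expect_gte(a$optimal_accuracy,
             a$points$cv_accuracy[nrow(a$points)])
})

test_that("IFS rejects a ranking from a different matrix", {
  fm <- separable_features(8, 8, p_noise = 2)
  other <- separable_features(8, 8, p_noise = 3)
  rk <- anova_f_scores(other)
  expect_error(
    incremental_feature_selection(fm, rk, grid = svm_config(1, 1)),
    "does not match")
})

test_that("IFS curve exports as two-column text", {
  fm <- separable_features(8, 8, p_noise = 2, seed = 6)
  rk <- anova_f_scores(fm)
  ifs <- incremental_feature_selection(fm, rk, grid = svm_config(8, 1),
                                       folds = 2, seed = 1)
  path <- tempfile(fileext = ".tsv")
  write_ifs_curve(ifs, path)
  back <- utils::read.delim(path)
  expect_equal(names(back), c("k", "cv_accuracy"))
  expect_equal(back$k, ifs$points$k)
})
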