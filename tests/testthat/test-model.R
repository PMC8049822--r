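test_that("compute_metrics reproduces hand-computed Sn/Sp/Acc", {
  m <- compute_metrics(c(TP = 3, FN = 1, TN = 4, FP = 2))
  expect_equal(unname(m), c(0.75, 4 / 6, 0.70))
  all_right <- compute_metrics(c(TP = 5, FN = 0, TN = 7, FP = 0))
  expect_equal(unname(all_right), c(1, 1, 1))
  # enumerated small confusion matrices against direct ratios
  for (TP in 0:3) for (FN in 0:3) for (TN in 0:3) for (FP in 0:3) {
    if (TP + FN == 0 || TN + FP == 0) next
    m <- compute_metrics(c(TP = TP, FN = FN, TN = TN, FP = FP))
    expect_equal(unname(m), c(TP / (TP + FN), TN / (TN + FP),
                              (TP + TN) / (TP + FN + TN + FP)))
  }
  expect_error(compute_metrics(c(TP = 0, FN = 0, TN = 4, FP = 2)),
               "undefined metric")
  expect_error(compute_metrics(c(TP = 2, FN = 1, TN = 0, FP = 0)),
               "undefined metric")
})

test_that("roc_auc handles the canonical cases", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "undefined AUC")
})

test_that("roc_auc equals the Mann-Whitney oracle on random vectors with ties", {
  set.seed(77)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    scores <- sample(round(rnorm(n), 1)) # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-9)
    # curve is anchored and monotone in fpr
    expect_equal(r$roc_points$fpr[1], 0)
    expect_equal(r$roc_points$tpr[1], 0)
    expect_equal(r$roc_points$fpr[nrow(r$roc_points)], 1)
    expect_equal(r$roc_points$tpr[nrow(r$roc_points)], 1)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
  }
})

test_that("grid helpers span the documented lattice", {
  g <- default_grid()
  expect_length(g, 90)
  Cs <- vapply(g, `[[`, 0, "C")
  gs <- vapply(g, `[[`, 0, "gamma")
  expect_true(all(Cs > 2^-5 & Cs < 2^15))
  expect_true(all(gs > 2^-15 & gs < 2^3))
  expect_error(svm_config(-1, 1))
  expect_error(svm_config(1, 0))
})

test_that("cross_validate separates a planted matrix perfectly and is deterministic", {
  fm <- separable_features(15, 25, p_noise = 2, seed = 10)
  ev1 <- cross_validate(fm, svm_config(8, 1), folds = 5, seed = 3)
  expect_equal(ev1$Acc, 1.0)
  expect_equal(ev1$AUC, 1.0)
  expect_equal(unname(ev1$confusion["TP"] + ev1$confusion["FN"]), 15)
  expect_equal(unname(ev1$confusion["TN"] + ev1$confusion["FP"]), 25)
  ev2 <- cross_validate(fm, svm_config(8, 1), folds = 5, seed = 3)
  expect_identical(ev1[c("confusion", "Sn", "Sp", "Acc", "AUC", "scores")],
                   ev2[c("confusion", "Sn", "Sp", "Acc", "AUC", "scores")])
})

test_that("stratified folds balance classes to within one sample", {
  y <- rep(c(1L, 0L), c(18, 42))
  fold_id <- raackit:::make_folds(y, 5, seed = 2)
  per_fold_pos <- tapply(y, fold_id, sum)
  per_fold_n <- tabulate(fold_id)
  expect_true(max(per_fold_pos) - min(per_fold_pos) <= 1)
  expect_true(max(per_fold_n) - min(per_fold_n) <= 2)
  expect_error(raackit:::make_folds(rep(c(1L, 0L), c(3, 40)), 5, 1),
               "stratification")
})

test_that("label permutation collapses accuracy to the null band", {
  fm <- separable_features(100, 100, p_noise = 2, seed = 12)
  set.seed(99)
  fm$labels <- sample(fm$labels)
  ev <- cross_validate(fm, svm_config(8, 1), folds = 5, seed = 3)
  expect_gte(ev$Acc, 0.35)
  expect_lte(ev$Acc, 0.65)
})

test_that("grid_search maximizes accuracy with smaller-C tie-breaks", {
  fm <- separable_features(12, 12, p_noise = 1, seed = 4)
  single <- grid_search(fm, list(svm_config(2, 0.5)), folds = 3, seed = 1)
  expect_equal(single$best$C, 2)
  gs <- grid_search(fm, coarse_grid(), folds = 3, seed = 1)
  expect_equal(nrow(gs$table), 9)
  expect_equal(gs$accuracy, max(gs$table$accuracy))
  # tie rule: among equally accurate configs, smallest C then gamma
  top <- gs$table[gs$table$accuracy == gs$accuracy, ]
  top <- top[order(top$C, top$gamma), ]
  expect_equal(gs$best$C, top$C[1])
  expect_equal(gs$best$gamma, top$gamma[1])
  expect_error(grid_search(fm, list()), "empty grid")
})

test_that("train/predict round-trips with provenance checks", {
  fm <- separable_features(15, 15, p_noise = 2, seed = 21)
  model <- train_final(fm, svm_config(8, 1))
  preds <- predict(model, fm)
  expect_equal(preds$class, fm$labels) # resubstitution on separable data
  # mismatched scheme is an encoding error
  other <- fm
  other$scheme <- parse_cluster_string("FWY-CILMV-DEGKNQS-AHPRT", 19L, 4L)
  expect_error(predict(model, other), "encoding mismatch")
  # save/load gives identical predictions
  path <- tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(predict(back, fm), preds, tolerance = 1e-12)
})

test_that("a model trained on selected features demands those features", {
  fm <- separable_features(10, 10, p_noise = 3, seed = 30)
  model <- train_final(fm, svm_config(8, 1), selected = c("F1", "F3"))
  expect_equal(model$feature_names, c("F1", "F3"))
  preds <- predict(model, fm)
  expect_equal(nrow(preds), 20)
})
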