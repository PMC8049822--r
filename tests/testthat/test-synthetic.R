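test_that("synthetic specs validate their invariants", {
  fam <- load_builtin_family()
  expect_s3_class(synthetic_spec(10, 10, fam[["10"]]), "raac_synth_spec")
  expect_error(synthetic_spec(0, 10, fam[["10"]]))
  expect_error(synthetic_spec(10, 10, fam[["10"]], N = 3), "N = 1 or 2")
  # infeasible tilt names the magnitude
  expect_error(synthetic_spec(10, 10, fam[["10"]], effect = 0.95),
               "infeasible tilt")
  # n_biased = 20 over 10 rows forces some row to carry two boosts, whose
  # stacked compensation drives another cell of that row below zero
  expect_error(
    generate_dataset(synthetic_spec(5, 5, fam[["10"]], N = 2, effect = 0.55,
                                    n_biased = 20, seed = 1)),
    "infeasible tilt")
  # benchmark shape mirrors the 1:6 imbalance
  bs <- benchmark_shaped_spec(seed = 3)
  expect_equal(bs$n_neg / bs$n_pos, 6)
  expect_equal(bs$scheme$size, 10)
  expect_equal(bs$N, 2)
})

test_that("identical specs generate byte-identical FASTA files", {
  spec <- synthetic_spec(8, 8, load_builtin_family()[["10"]], seed = 99,
                         length_range = c(30, 60))
  a <- generate_dataset(spec, dir = tempfile())
  b <- generate_dataset(spec, dir = tempfile())
  expect_identical(readBin(a$positive_path, "raw", 1e6),
                   readBin(b$positive_path, "raw", 1e6))
  expect_identical(readBin(a$negative_path, "raw", 1e6),
                   readBin(b$negative_path, "raw", 1e6))
  # and the global RNG stream is left untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); generate_dataset(spec, dir = tempfile()); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("generated datasets parse back with the declared shape", {
  spec <- benchmark_shaped_spec(seed = 11)
  ds <- generate_dataset(spec, dir = tempfile())
  rec <- read_labeled_fasta(ds$positive_path, ds$negative_path)
  expect_equal(sum(rec$label == 1L), 40)
  expect_equal(sum(rec$label == 0L), 240)
  lens <- nchar(rec$sequence)
  expect_true(all(lens >= 50 & lens <= 300))
  expect_true(all(strsplit(paste(rec$sequence, collapse = ""), "")[[1]]
                  %in% AA20_TEST))
  expect_equal(nrow(ds$manifest), 20) # one row per biased feature
  expect_true(all(ds$manifest$biased_feature %in%
                    npeptide_feature_names(spec$scheme$labels, 2)))
})

test_that("a strong planted signal is separable and a null one is not", {
  fam <- load_builtin_family()
  cfg <- svm_config(32, "scale")
  # near-disjoint transition supports: high accuracy by construction
  strong <- synthetic_spec(50, 50, fam[["10"]], effect = 0.5, n_biased = 5,
                           length_range = c(50, 300), seed = 21)
  ds <- generate_dataset(strong, dir = tempfile())
  feats <- encode_dataset(ds$records, fam[["10"]], 2)
  ev <- cross_validate(feats, cfg, folds = 5, seed = 2)
  expect_gte(ev$Acc, 0.95)
  # effect = 0: exchangeable classes, accuracy in the balanced null band
  null <- synthetic_spec(100, 100, fam[["10"]], effect = 0,
                         length_range = c(50, 300), seed = 22)
  ds0 <- generate_dataset(null, dir = tempfile())
  feats0 <- encode_dataset(ds0$records, fam[["10"]], 2)
  ev0 <- cross_validate(feats0, cfg, folds = 5, seed = 2)
  expect_gte(ev0$Acc, 0.35)
  expect_lte(ev0$Acc, 0.65)
})

test_that("ANOVA ranks recover planted features", {
  # at the strong-signal setting, at least half of the manifest's biased
  # features must appear within the top 2 * n_biased ranks
  spec <- synthetic_spec(60, 60, load_builtin_family()[["10"]], seed = 41)
  ds <- generate_dataset(spec, dir = tempfile())
  feats <- encode_dataset(ds$records, load_builtin_family()[["10"]], 2)
  rk <- anova_f_scores(feats)
  top <- rk$entries$feature[seq_len(2 * spec$n_biased)]
  hits <- sum(ds$manifest$biased_feature %in% top)
  expect_gte(hits, spec$n_biased / 2)
})

test_that("IFS optimum on null data stays inside its permutation null", {
  fam <- load_builtin_family()
  spec <- synthetic_spec(30, 30, fam[["4"]], N = 1, effect = 0,
                         n_biased = 2, length_range = c(50, 120), seed = 55)
  ds <- generate_dataset(spec, dir = tempfile())
  feats <- encode_dataset(ds$records, fam[["4"]], 1)
  cfg <- svm_config(32, "scale")
  run_ifs <- function(f) {
    rk <- anova_f_scores(f)
    incremental_feature_selection(f, rk, grid = cfg, folds = 3,
                                  seed = 9)$optimal_accuracy
  }
  observed <- run_ifs(feats)
  set.seed(77)
  null_dist <- replicate(19, {
    perm <- feats
    perm$labels <- sample(perm$labels)
    run_ifs(perm)
  })
  expect_lte(observed, stats::quantile(null_dist, 0.95) + 1e-12)
})
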