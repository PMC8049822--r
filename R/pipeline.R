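#' Scan reduced-alphabet schemes and N-peptide orders
#'
#' Evaluates cross-validated accuracy of the RBF SVM for every
#' (scheme, N) combination on the full (pre-selection) feature set. The
#' winner is the row with maximum accuracy; ties prefer the smaller
#' alphabet, then the smaller N (simpler encodings win). A combination
#' whose encoding fails (e.g. every sequence too short) is recorded as
#' failed, not fatal.
#'
#' @param records Labeled dataset (data.frame `id`, `sequence`, `label`).
#' @param schemes List of `raac_scheme` (default: the bundled family).
#' @param n_set Subset of `c(1, 2, 3)`.
#' @param grid A `raac_svm_config` or list of them; the default single
#'   moderate configuration keeps the scan fast — run [grid_search()] on the
#'   winner afterwards for full tuning.
#' @param folds,seed Cross-validation parameters, shared by all rows.
#' @param cv_repeats Number of repeated cross-validation rounds per row
#'   (default 3). Each round uses folds re-shuffled with a seed derived from
#'   `seed`, identically across rows, and the row's accuracy is the mean —
#'   model selection over 50+ highly correlated encodings is sensitive to
#'   single-shuffle noise, which repetition averages out.
#' @return An object of class `raac_scan`: data.frame `rows` with columns
#'   `type_id`, `size`, `N`, `n_features`, `cv_accuracy`, `C`, `gamma`,
#'   `status`; plus `winner` (the arg-max row) and `seed`.
#' @export
scheme_scan <- function(records, schemes = load_builtin_family(),
                        n_set = c(1L, 2L, 3L), grid = scan_config(),
                        folds = 5L, seed = 1L, cv_repeats = 3L) {
  stopifnot(length(schemes) >= 1L, length(n_set) >= 1L,
            all(n_set %in% 1:3), cv_repeats >= 1L)
  if (inherits(grid, "raac_svm_config")) grid <- list(grid)
  fold_seeds <- vapply(seq_len(cv_repeats), function(r) {
    as.integer((as.numeric(seed) * 100 + r) %% 2147483647)
  }, 0L)
  rows <- vector("list", length(schemes) * length(n_set))
  i <- 0L
  for (sch in schemes) {
    for (N in sort(as.integer(n_set))) {
      i <- i + 1L
      row <- data.frame(type_id = sch$type_id, size = sch$size, N = N,
                        n_features = sch$size^N, cv_accuracy = NA_real_,
                        C = NA_real_, gamma = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        feats <- suppressMessages(encode_dataset(records, sch, N))
        grid_r <- lapply(grid, resolve_config, x = feats$x)
        y <- feats$labels
        d2 <- d2_matrix(feats$x)
        acc_mat <- vapply(fold_seeds, function(fs) {
          fold_id <- make_folds(y, folds, fs)
          vapply(cv_scores_engine(NULL, y, grid_r, fold_id, d2 = d2),
                 function(s) mean((s > 0) == (y == 1L)), 0)
        }, numeric(length(grid_r)))
        acc <- rowMeans(matrix(acc_mat, nrow = length(grid_r)))
        b <- order(-acc, vapply(grid_r, `[[`, 0, "C"),
                   vapply(grid_r, `[[`, 0, "gamma"))[1]
        list(acc = acc[b], C = grid_r[[b]]$C, gamma = grid_r[[b]]$gamma)
      }, error = function(e) conditionMessage(e))
      if (is.list(res)) {
        row$cv_accuracy <- res$acc
        row$C <- res$C
        row$gamma <- res$gamma
      } else {
        row$status <- paste0("failed: ", res)
      }
      rows[[i]] <- row
    }
  }
  rows <- do.call(rbind, rows)
  ok <- which(!is.na(rows$cv_accuracy))
  if (!length(ok)) stop("every (scheme, N) combination failed", call. = FALSE)
  ord <- ok[order(-rows$cv_accuracy[ok], rows$size[ok], rows$N[ok])]
  structure(list(rows = rows, winner = rows[ord[1], , drop = FALSE],
                 seed = seed),
            class = "raac_scan")
}

#' @export
print.raac_scan <- function(x, ...) {
  w <- x$winner
  cat(sprintf(
    "Scheme scan: %d rows; winner size %d, N = %d (Acc %.4f)\n",
    nrow(x$rows), w$size, w$N, w$cv_accuracy))
  invisible(x)
}

#' Write a scan table as delimited text
#'
#' @param scan A `raac_scan`.
#' @param path Output path.
#' @export
write_scan_table <- function(scan, path) {
  stopifnot(inherits(scan, "raac_scan"))
  utils::write.table(
    format(scan$rows, digits = 15, scientific = FALSE, trim = TRUE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param positive_path,negative_path Input FASTA files.
#' @param scheme_catalog Optional catalog file; by default the bundled
#'   family is scanned.
#' @param n_set Subset of `c(1, 2, 3)`.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Root seed for every stochastic step.
#' @param scan_grid,final_grid Configurations for the scan and for tuning
#'   the winner.
#' @param ifs Run incremental feature selection on the winner?
#' @param ifs_max_features Cap on IFS prefix length (keeps desk-scale
#'   runtime bounded; `NULL` = all features).
#' @param out_dir Output directory for artifacts.
#' @return An object of class `raac_run_config`.
#' @export
run_config <- function(positive_path, negative_path, scheme_catalog = NULL,
                       n_set = c(1L, 2L, 3L), folds = 5L, seed = 1L,
                       scan_grid = scan_config(), final_grid = coarse_grid(),
                       ifs = TRUE, ifs_max_features = 100L,
                       out_dir = "raackit_run") {
  stopifnot(length(n_set) >= 1L, all(n_set %in% 1:3), folds >= 2L)
  structure(
    list(positive_path = positive_path, negative_path = negative_path,
         scheme_catalog = scheme_catalog, n_set = as.integer(n_set),
         folds = as.integer(folds), seed = as.integer(seed),
         scan_grid = scan_grid, final_grid = final_grid, ifs = isTRUE(ifs),
         ifs_max_features = ifs_max_features, out_dir = out_dir),
    class = "raac_run_config"
  )
}

# 32-bit FNV-1a over the deparsed config, for stamping artifacts. The hash
# state lives in a double, so the xor with the input byte is done on the low
# 8 bits by modular arithmetic (bitwXor would overflow R's integers).
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config[setdiff(names(config), "out_dir")]),
                           collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- h - h %% 256 + bitwXor(h %% 256, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full scan / select / train pipeline
#'
#' Reads the labeled FASTA pair, scans (scheme, N) combinations, tunes
#' C and gamma on the winner, optionally runs incremental feature selection,
#' cross-validates the final configuration and trains the final model on all
#' data. Writes five artifacts under `config$out_dir`: `scan_table.tsv`,
#' `ifs_curve.tsv` (when IFS is on), `final_report.txt`, `model.json`,
#' `run_log.txt`, each stamped with the config hash and seed. Re-running an
#' identical config reproduces identical bytes.
#'
#' @param config A `raac_run_config`.
#' @return Invisibly, a list with `scan`, `ifs`, `evaluation`, `model` and
#'   the artifact paths.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "raac_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_lines <- c(sprintf("raackit pipeline run | config %s | seed %d",
                         hash, config$seed))
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  records <- read_labeled_fasta(config$positive_path, config$negative_path)
  say("read %d records (%d positive, %d negative)", nrow(records),
      sum(records$label == 1L), sum(records$label == 0L))

  schemes <- if (is.null(config$scheme_catalog)) load_builtin_family()
             else load_catalog(config$scheme_catalog)
  scan <- scheme_scan(records, schemes, config$n_set,
                      grid = config$scan_grid, folds = config$folds,
                      seed = config$seed)
  scan_path <- file.path(config$out_dir, "scan_table.tsv")
  write_scan_table(scan, scan_path)
  w <- scan$winner
  say("scan: %d rows; winner type %d size %d N %d (Acc %.6f)",
      nrow(scan$rows), w$type_id, w$size, w$N, w$cv_accuracy)

  win_scheme <- Filter(function(s) s$type_id == w$type_id & s$size == w$size,
                       schemes)[[1]]
  feats <- suppressMessages(encode_dataset(records, win_scheme, w$N))

  gs <- grid_search(feats, config$final_grid, folds = config$folds,
                    seed = config$seed)
  say("grid search on winner: C = 2^%g, gamma = 2^%g (Acc %.6f)",
      log2(gs$best$C), log2(gs$best$gamma), gs$accuracy)

  ifs_res <- NULL
  ifs_path <- NULL
  selected <- feats$feature_names
  if (config$ifs) {
    ranking <- anova_f_scores(feats)
    ifs_res <- incremental_feature_selection(
      feats, ranking, grid = gs$best, folds = config$folds,
      seed = config$seed, max_features = config$ifs_max_features)
    selected <- ranking$entries$feature[seq_len(ifs_res$optimal_k)]
    ifs_path <- file.path(config$out_dir, "ifs_curve.tsv")
    write_ifs_curve(ifs_res, ifs_path)
    say("IFS: optimal k = %d (Acc %.6f)", ifs_res$optimal_k,
        ifs_res$optimal_accuracy)
  } else {
    say("IFS disabled: final model uses all %d winner features",
        length(selected))
  }

  final_feats <- subset_features(feats, selected)
  evaluation <- cross_validate(final_feats, gs$best, folds = config$folds,
                               seed = config$seed)
  model <- train_final(feats, gs$best, selected = selected,
                       seed = config$seed)
  model_path <- file.path(config$out_dir, "model.json")
  save_model(model, model_path)

  report_path <- file.path(config$out_dir, "final_report.txt")
  write_report(evaluation, report_path,
               header = c(
                 sprintf("config_hash\t%s", hash),
                 sprintf("seed\t%d", config$seed),
                 sprintf("scheme\t%s", model$scheme_notation),
                 sprintf("scheme_size\t%d", model$scheme_size),
                 sprintf("N\t%d", model$N),
                 sprintf("n_features\t%d", length(selected)),
                 sprintf("ifs\t%s", if (config$ifs) "on" else "off")))

  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)

  invisible(list(scan = scan, ifs = ifs_res, evaluation = evaluation,
                 model = model,
                 paths = list(scan_table = scan_path, ifs_curve = ifs_path,
                              report = report_path, model = model_path,
                              log = log_path)))
}

# Structured-text evaluation report: key-value block then ROC point table.
write_report <- function(evaluation, path, header = character(0)) {
  stopifnot(inherits(evaluation, "raac_eval"))
  cf <- evaluation$confusion
  kv <- c(
    header,
    sprintf("folds\t%d", evaluation$folds),
    sprintf("C\t%.10g", evaluation$config$C),
    sprintf("gamma\t%.10g", evaluation$config$gamma),
    sprintf("TP\t%d", cf["TP"]), sprintf("FN\t%d", cf["FN"]),
    sprintf("TN\t%d", cf["TN"]), sprintf("FP\t%d", cf["FP"]),
    sprintf("Sn\t%.6f", evaluation$Sn),
    sprintf("Sp\t%.6f", evaluation$Sp),
    sprintf("Acc\t%.6f", evaluation$Acc),
    sprintf("AUC\t%.6f", evaluation$AUC),
    "", "fpr\ttpr"
  )
  roc <- sprintf("%.6f\t%.6f", evaluation$roc_points$fpr,
                 evaluation$roc_points$tpr)
  writeLines(c(kv, roc), path)
  invisible(path)
}

#' Evaluate a saved model on an independent labeled dataset
#'
#' Encodes the independent sequences with the model's stored scheme and N,
#' restricts to the model's selected features, and reports confusion
#' counts, Sn/Sp/Acc and AUC from the decision scores.
#'
#' @param model_path Path to a model saved by [save_model()] (or a
#'   `raac_model` object).
#' @param positive_path,negative_path Independent FASTA files.
#' @return List with `confusion`, `Sn`, `Sp`, `Acc`, `AUC`, `predictions`
#'   (per-sample data.frame).
#' @export
evaluate_independent <- function(model_path, positive_path, negative_path) {
  model <- if (inherits(model_path, "raac_model")) model_path
           else load_model(model_path)
  records <- read_labeled_fasta(positive_path, negative_path)
  if (!any(records$label == 1L)) {
    stop("undefined Sn: independent set has no positive samples",
         call. = FALSE)
  }
  if (!any(records$label == 0L)) {
    stop("undefined Sp: independent set has no negative samples",
         call. = FALSE)
  }
  scheme <- parse_cluster_string(model$scheme_notation,
                                 type_id = model$scheme_type,
                                 size = model$scheme_size)
  feats <- suppressMessages(encode_dataset(records, scheme, model$N))
  preds <- predict(model, feats)
  y <- feats$labels
  cf <- c(TP = sum(preds$class == 1L & y == 1L),
          TN = sum(preds$class == 0L & y == 0L),
          FP = sum(preds$class == 1L & y == 0L),
          FN = sum(preds$class == 0L & y == 1L))
  metrics <- compute_metrics(cf)
  roc <- roc_auc(preds$score, y)
  preds$label <- y
  list(confusion = cf, Sn = unname(metrics["Sn"]), Sp = unname(metrics["Sp"]),
       Acc = unname(metrics["Acc"]), AUC = roc$auc, predictions = preds)
}
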