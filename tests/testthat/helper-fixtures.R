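# Shared fixtures and independent oracles used across test files.

AA20_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len, alphabet = AA20_TEST) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force N-peptide oracle: enumerate every overlapping window with
# substring() and tally the window strings against the feature names.
# Independent of the integer k-mer indexing used by the implementation.
oracle_npeptide <- function(reduced, alphabet, N) {
  L <- nchar(reduced)
  windows <- substring(reduced, seq_len(L - N + 1L), seq_len(L - N + 1L) + N - 1L)
  feats <- npeptide_feature_names(alphabet, N)
  counts <- table(factor(windows, levels = feats))
  as.numeric(counts) / (L - N + 1L)
}

# Closed-form two-group one-way ANOVA oracle on a single feature.
oracle_anova_f <- function(x_pos, x_neg) {
  n1 <- length(x_pos); n0 <- length(x_neg); n <- n1 + n0
  m1 <- mean(x_pos); m0 <- mean(x_neg)
  grand <- mean(c(x_pos, x_neg))
  ssb <- n1 * (m1 - grand)^2 + n0 * (m0 - grand)^2
  ssw <- sum((x_pos - m1)^2) + sum((x_neg - m0)^2)
  msw <- ssw / (n - 2)
  if (msw > 0) ssb / msw else if (ssb > 0) Inf else 0
}

# Mann-Whitney oracle for AUC: P(s+ > s-) + 0.5 P(s+ = s-) over all
# positive-negative pairs.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Small labeled FASTA pair on disk; returns the two paths.
write_fasta_pair <- function(pos_seqs, neg_seqs, dir = tempfile("fa")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos <- file.path(dir, "pos.fasta")
  neg <- file.path(dir, "neg.fasta")
  writeLines(paste0(">p", seq_along(pos_seqs), "\n", pos_seqs), pos)
  writeLines(paste0(">n", seq_along(neg_seqs), "\n", neg_seqs), neg)
  list(pos = pos, neg = neg)
}

# A feature matrix with one perfectly separating column and `p_noise`
# uniform-noise columns, wrapped as raac_features for model-level tests.
separable_features <- function(n_pos = 20, n_neg = 20, p_noise = 4,
                               seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  labels <- c(rep(1L, n_pos), rep(0L, n_neg))
  x <- cbind(ifelse(labels == 1L, 1, 0) + rnorm(n, sd = 0.05),
             matrix(runif(n * p_noise), n, p_noise))
  colnames(x) <- paste0("F", seq_len(p_noise + 1L))
  scheme <- parse_cluster_string("CFILMVWY-ADEGHKNPQRST", 19L, 2L)
  structure(
    list(x = x, sample_ids = paste0("s", seq_len(n)),
         feature_names = colnames(x), labels = labels,
         scheme = scheme, N = 1L, excluded = character(0)),
    class = "raac_features"
  )
}
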