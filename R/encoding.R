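#' Read a labeled binary-class dataset from two FASTA files
#'
#' Records from `positive_path` are labeled 1, records from `negative_path`
#' 0. Sequences are normalized to uppercase. Ids duplicated across the two
#' files are disambiguated with a `|pos` / `|neg` suffix and a warning.
#'
#' @param positive_path FASTA file of positive-class sequences.
#' @param negative_path FASTA file of negative-class sequences.
#' @return A data.frame with columns `id`, `sequence`, `label` (integer 1/0),
#'   one row per record, in file order (positives first).
#' @export
read_labeled_fasta <- function(positive_path, negative_path) {
  pos <- read_fasta_file(positive_path)
  neg <- read_fasta_file(negative_path)
  if (nrow(pos) + nrow(neg) == 0L) {
    stop("empty dataset: no FASTA records in either file", call. = FALSE)
  }
  dup <- intersect(pos$id, neg$id)
  if (length(dup)) {
    warning("duplicate ids across files, disambiguated: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) " ...", call. = FALSE)
    pos$id[pos$id %in% dup] <- paste0(pos$id[pos$id %in% dup], "|pos")
    neg$id[neg$id %in% dup] <- paste0(neg$id[neg$id %in% dup], "|neg")
  }
  out <- rbind(
    data.frame(id = pos$id, sequence = pos$sequence,
               label = rep(1L, nrow(pos)), stringsAsFactors = FALSE),
    data.frame(id = neg$id, sequence = neg$sequence,
               label = rep(0L, nrow(neg)), stringsAsFactors = FALSE)
  )
  rownames(out) <- NULL
  out
}

# Biostrings does the FASTA parsing; this wrapper normalizes case, checks
# the leading '>' explicitly, and returns a plain data.frame.
read_fasta_file <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && nzchar(first) && substr(first, 1, 1) != ">") {
    stop("format error in ", path, ": file does not start with '>'",
         call. = FALSE)
  }
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("format error reading FASTA ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(aa))
  ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  data.frame(id = ids, sequence = toupper(as.character(aa)),
             stringsAsFactors = FALSE)
}

#' N-peptide feature names for a reduced alphabet
#'
#' All length-`N` words over `labels`, ordered lexicographically in the
#' alphabet's own label order (first position most significant). This fixed
#' order makes saved models portable across runs.
#'
#' @param labels Ordered character vector of single-character group labels.
#' @param N Word length (1, 2 or 3).
#' @return Character vector of length `length(labels)^N`.
#' @export
npeptide_feature_names <- function(labels, N) {
  stopifnot(N %in% 1:3)
  k <- length(labels)
  idx <- seq_len(k)
  if (N == 1L) return(labels)
  grid <- do.call(expand.grid, rev(replicate(N, idx, simplify = FALSE)))
  grid <- grid[, rev(seq_len(N)), drop = FALSE] # first position slowest
  apply(grid, 1L, function(r) paste(labels[r], collapse = ""))
}

#' Overlapping N-peptide composition of a reduced sequence
#'
#' For a sequence of length L over the reduced alphabet, the frequency of
#' each length-N word w is `count(w, overlapping) / (L - N + 1)`; the vector
#' sums to 1 and has `length(alphabet)^N` entries in the order of
#' [npeptide_feature_names()].
#'
#' @param reduced String over the scheme's group labels.
#' @param alphabet Ordered character vector of group labels.
#' @param N Word length (1, 2 or 3).
#' @return Named numeric frequency vector.
#' @examples
#' npeptide_composition("AAAB", c("A", "B"), 2) # AA 2/3, AB 1/3, BA 0, BB 0
#' @export
npeptide_composition <- function(reduced, alphabet, N) {
  stopifnot(is.character(reduced), length(reduced) == 1L, N %in% 1:3)
  k <- length(alphabet)
  L <- nchar(reduced)
  if (L < N) {
    stop("short sequence: length ", L, " < N = ", N, call. = FALSE)
  }
  codes <- match(strsplit(reduced, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(codes)) {
    stop("encoding error: symbol outside alphabet in reduced sequence",
         call. = FALSE)
  }
  counts <- count_npeptides(codes, k, N)
  out <- counts / (L - N + 1)
  names(out) <- npeptide_feature_names(alphabet, N)
  out
}

# Integer k-mer indexing: word (c1..cN) -> ((c1-1)*k + (c2-1))*k + ... + 1,
# matching the first-position-major feature order.
count_npeptides <- function(codes, k, N) {
  L <- length(codes)
  n_win <- L - N + 1L
  idx <- codes[seq_len(n_win)] - 1L
  if (N >= 2L) {
    for (j in 2:N) idx <- idx * k + (codes[seq_len(n_win) + (j - 1L)] - 1L)
  }
  tabulate(idx + 1L, nbins = k^N)
}

#' Encode a labeled dataset as an N-peptide composition feature matrix
#'
#' Each sequence is reduced under `scheme` (non-standard residues skipped)
#' and converted to its overlapping N-peptide frequency vector. Sequences
#' whose reduced length is below `N` are excluded and their ids recorded.
#'
#' @param records Data.frame with columns `id`, `sequence`, `label`
#'   (as from [read_labeled_fasta()]).
#' @param scheme A `raac_scheme`.
#' @param N Word length (1, 2 or 3).
#' @return An object of class `raac_features`: list with `x` (numeric matrix,
#'   samples x size^N), `sample_ids`, `feature_names`, `labels` (integer 1/0),
#'   `scheme`, `N`, `excluded` (character ids dropped as too short).
#' @export
encode_dataset <- function(records, scheme, N) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("id", "sequence", "label") %in% names(records)),
            inherits(scheme, "raac_scheme"), N %in% 1:3)
  if (anyDuplicated(records$id)) {
    stop("duplicate sample ids in records", call. = FALSE)
  }
  k <- scheme$size
  fn <- npeptide_feature_names(scheme$labels, N)
  n <- nrow(records)
  x <- matrix(0, nrow = n, ncol = k^N)
  keep <- logical(n)
  for (i in seq_len(n)) {
    red <- tryCatch(reduce_sequence(records$sequence[i], scheme, "skip"),
                    error = function(e) "")
    if (nchar(red) < N) next
    codes <- match(strsplit(red, "", fixed = TRUE)[[1]], scheme$labels)
    cnt <- count_npeptides(codes, k, N)
    x[i, ] <- cnt / (nchar(red) - N + 1L)
    keep[i] <- TRUE
  }
  if (!any(keep)) {
    stop("empty matrix: every sequence too short for N = ", N, call. = FALSE)
  }
  excluded <- records$id[!keep]
  if (length(excluded)) {
    message("excluded ", length(excluded), " sequence(s) shorter than N = ",
            N, ": ", paste(utils::head(excluded, 5), collapse = ", "))
  }
  x <- x[keep, , drop = FALSE]
  colnames(x) <- fn
  rownames(x) <- records$id[keep]
  structure(
    list(x = x, sample_ids = records$id[keep], feature_names = fn,
         labels = as.integer(records$label[keep]),
         scheme = scheme, N = as.integer(N), excluded = excluded),
    class = "raac_features"
  )
}

#' @export
print.raac_features <- function(x, ...) {
  cat(sprintf(
    "N-peptide feature matrix: %d samples x %d features (scheme size %d, N = %d)\n  %d positive / %d negative%s\n",
    nrow(x$x), ncol(x$x), x$scheme$size, x$N,
    sum(x$labels == 1L), sum(x$labels == 0L),
    if (length(x$excluded)) sprintf("; %d excluded", length(x$excluded)) else ""
  ))
  invisible(x)
}

#' Write a feature matrix as delimited text
#'
#' Header row of feature names, first column `id`, last column `label`.
#'
#' @param features A `raac_features` object.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @export
write_features <- function(features, path, sep = "\t") {
  stopifnot(inherits(features, "raac_features"))
  df <- data.frame(id = features$sample_ids, features$x,
                   label = features$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Restrict a feature matrix to a subset of named features (used by IFS and
# by prediction with a trained model).
subset_features <- function(features, feature_names) {
  miss <- setdiff(feature_names, features$feature_names)
  if (length(miss)) {
    stop("encoding mismatch: feature(s) absent from matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  features$x <- features$x[, feature_names, drop = FALSE]
  features$feature_names <- feature_names
  features
}
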