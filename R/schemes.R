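#' @useDynLib raackit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats predict
NULL

# The 20 standard one-letter amino acid codes, alphabetical.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity / non-standard codes tolerated on input (dropped or rejected
# according to the unknown policy).
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z", "*")

# Information-maximization reduction family, sizes 2 through 19.
# Each entry is the dash-delimited cluster notation; groups are ordered and
# each group's label is its first letter.
.builtin_clusters <- c(
  "2"  = "CFILMVWY-ADEGHKNPQRST",
  "3"  = "CFILMVWY-DEGKNQS-AHPRT",
  "4"  = "FWY-CILMV-DEGKNQS-AHPRT",
  "5"  = "FWY-CILMV-DEGKNS-APQT-HR",
  "6"  = "FWY-CILMV-DE-GKNQS-APT-HR",
  "7"  = "FWY-CILMV-DE-K-GNPQS-AT-HR",
  "8"  = "FWY-ILMV-C-DE-K-GNPQS-AT-HR",
  "9"  = "FWY-ILMV-C-DE-K-GNQS-PT-A-HR",
  "10" = "WY-F-ILMV-C-DE-K-GNQS-PT-A-HR",
  "11" = "WY-F-ILMV-C-DE-K-G-PNQS-T-A-HR",
  "12" = "WY-F-IL-MV-C-DE-K-G-PNQS-T-A-HR",
  "13" = "WY-F-IL-MV-C-DE-K-G-P-NQS-T-A-HR",
  "14" = "W-Y-F-IL-MV-C-DE-K-G-P-NQS-T-A-HR",
  "15" = "W-Y-F-IL-MV-C-DE-K-G-P-NQS-T-A-H-R",
  "16" = "W-Y-F-IL-M-V-C-DE-K-G-P-NQS-T-A-H-R",
  "17" = "W-Y-F-I-L-M-V-C-DE-K-G-P-NQS-T-A-H-R",
  "18" = "W-Y-F-I-L-M-V-C-DE-K-G-P-N-QS-T-A-H-R",
  "19" = "W-Y-F-I-L-M-V-C-D-E-K-G-P-N-QS-T-A-H-R"
)

#' Parse a reduced amino acid alphabet from cluster notation
#'
#' A reduction scheme is an ordered partition of the 20 standard amino acids
#' into `size` groups, written as dash-delimited clusters, e.g.
#' `"WY-F-ILMV-C-DE-K-GNQS-PT-A-HR"` for a 10-letter alphabet. Each group's
#' single-character label is, by convention, the first letter of the group.
#'
#' @param notation Dash-delimited cluster string over the 20 standard
#'   one-letter codes (uppercase).
#' @param type_id Integer scheme-family identifier (catalog "type").
#' @param size Declared number of groups; must equal the number of
#'   dash-separated tokens.
#' @return An object of class `raac_scheme`: a list with `type_id`, `size`,
#'   `groups` (character vector of clusters, in order) and `labels`
#'   (single-character group labels, pairwise distinct).
#' @examples
#' sch <- parse_cluster_string("CFILMVWY-ADEGHKNPQRST", type_id = 19, size = 2)
#' sch$labels # "C" "A"
#' @export
parse_cluster_string <- function(notation, type_id, size) {
  stopifnot(is.character(notation), length(notation) == 1L, nzchar(notation))
  type_id <- as.integer(type_id)
  size <- as.integer(size)
  if (grepl("[^A-Z-]", notation)) {
    stop("illegal character in cluster notation: ",
         gsub("[A-Z-]", "", notation), call. = FALSE)
  }
  groups <- strsplit(notation, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(groups))) {
    stop("empty group in cluster notation '", notation, "'", call. = FALSE)
  }
  if (length(groups) != size) {
    stop("size mismatch: notation has ", length(groups),
         " groups but declared size is ", size, call. = FALSE)
  }
  letters_all <- unlist(strsplit(groups, "", fixed = TRUE))
  bad <- setdiff(letters_all, AA20)
  if (length(bad)) {
    stop("non-standard amino acid code(s) in notation: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  dup <- unique(letters_all[duplicated(letters_all)])
  if (length(dup)) {
    stop("partition error: amino acid(s) assigned to more than one group: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(AA20, letters_all)
  if (length(missing)) {
    stop("partition error: amino acid(s) unassigned: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- substr(groups, 1L, 1L)
  if (anyDuplicated(labels)) {
    stop("group labels not distinct for notation '", notation, "'",
         call. = FALSE)
  }
  structure(
    list(type_id = type_id, size = size, groups = groups, labels = labels),
    class = "raac_scheme"
  )
}

#' @export
print.raac_scheme <- function(x, ...) {
  cat(sprintf("Reduced amino acid alphabet (type %d, size %d)\n  %s\n",
              x$type_id, x$size, format_scheme(x)))
  invisible(x)
}

#' Format a scheme back to its dash-delimited cluster notation
#'
#' Inverse of [parse_cluster_string()] on the notation string.
#'
#' @param scheme A `raac_scheme`.
#' @return The cluster notation string.
#' @export
format_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "raac_scheme"))
  paste(scheme$groups, collapse = "-")
}

#' Rewrite an amino acid sequence over a reduced alphabet
#'
#' Each standard residue is replaced by the label of the group containing it.
#' Non-standard codes (B, J, O, U, X, Z and `*`) are dropped with a count
#' reported (`unknown_policy = "skip"`, the default) or raise an error naming
#' the first offending position (`unknown_policy = "error"`). Input is
#' case-insensitive.
#'
#' @param sequence Amino acid string (length-1 character).
#' @param scheme A `raac_scheme`.
#' @param unknown_policy `"skip"` or `"error"`.
#' @return The reduced string, with attribute `dropped` giving the number of
#'   non-standard residues removed.
#' @examples
#' s2 <- parse_cluster_string("CFILMVWY-ADEGHKNPQRST", 19, 2)
#' reduce_sequence("ACDF", s2) # "ACAC"
#' @export
reduce_sequence <- function(sequence, scheme,
                            unknown_policy = c("skip", "error")) {
  stopifnot(inherits(scheme, "raac_scheme"),
            is.character(sequence), length(sequence) == 1L)
  unknown_policy <- match.arg(unknown_policy)
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  seq_up <- toupper(sequence)
  if (grepl("[^A-Z*]", seq_up)) {
    stop("sequence contains non-amino-acid characters", call. = FALSE)
  }
  nonstd <- gsub(paste0("[", paste(AA20, collapse = ""), "]"), "", seq_up)
  n_drop <- nchar(nonstd)
  if (n_drop > 0L) {
    if (unknown_policy == "error") {
      pos <- regexpr(paste0("[^", paste(AA20, collapse = ""), "]"), seq_up)
      stop(sprintf("non-standard residue '%s' at position %d",
                   substr(seq_up, pos, pos), pos), call. = FALSE)
    }
    seq_up <- gsub(paste0("[^", paste(AA20, collapse = ""), "]"), "", seq_up)
    if (!nzchar(seq_up)) {
      stop("degenerate sequence: empty after dropping non-standard residues",
           call. = FALSE)
    }
  }
  # chartr maps every standard letter to its group label in one pass
  from <- paste(unlist(strsplit(scheme$groups, "", fixed = TRUE)),
                collapse = "")
  to <- paste(rep(scheme$labels, nchar(scheme$groups)), collapse = "")
  out <- chartr(from, to, seq_up)
  attr(out, "dropped") <- n_drop
  out
}

#' Load the bundled information-maximization reduction family
#'
#' Eighteen schemes of sizes 2 through 19, derived by maximizing the mutual
#' information of paired residue contacts; the coarse end merges
#' physicochemically similar residues (aromatics FWY, aliphatics+sulfur
#' CILMV, acids DE, bases HR, small AT, polar NQS) and the size-19 scheme
#' keeps only Q and S merged.
#'
#' @return A named list of 18 `raac_scheme` objects; names are the sizes
#'   `"2"` ... `"19"`.
#' @export
load_builtin_family <- function() {
  sizes <- as.integer(names(.builtin_clusters))
  schemes <- mapply(function(notation, size) {
    parse_cluster_string(notation, type_id = 19L, size = size)
  }, .builtin_clusters, sizes, SIMPLIFY = FALSE)
  names(schemes) <- names(.builtin_clusters)
  schemes
}

#' Load a scheme catalog from a plain-text file
#'
#' One record per line, whitespace-separated: `type size cluster-notation`.
#' Blank lines and `#` comments are ignored. Every record is validated as a
#' full partition of the 20 standard amino acids; duplicate (type, size)
#' pairs are rejected.
#'
#' @param path Path to the catalog file.
#' @return A list of `raac_scheme` objects (possibly empty).
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  schemes <- vector("list", length(keep))
  seen <- character(0)
  for (j in seq_along(keep)) {
    i <- keep[j]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 3L) {
      stop(sprintf("catalog parse error at line %d: expected 'type size clusters', got %d field(s)",
                   i, length(fields)), call. = FALSE)
    }
    type_id <- suppressWarnings(as.integer(fields[1]))
    size <- suppressWarnings(as.integer(fields[2]))
    if (is.na(type_id) || is.na(size)) {
      stop(sprintf("catalog parse error at line %d: non-integer type or size", i),
           call. = FALSE)
    }
    sch <- tryCatch(
      parse_cluster_string(fields[3], type_id = type_id, size = size),
      error = function(e) {
        stop(sprintf("catalog record at line %d (type %d, size %d): %s",
                     i, type_id, size, conditionMessage(e)), call. = FALSE)
      }
    )
    key <- paste(type_id, size, sep = ":")
    if (key %in% seen) {
      stop(sprintf("duplicate catalog record (type %d, size %d) at line %d",
                   type_id, size, i), call. = FALSE)
    }
    seen <- c(seen, key)
    schemes[[j]] <- sch
  }
  schemes
}
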