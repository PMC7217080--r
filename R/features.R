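#' Construct datasets
#'
#' A construct dataset holds engineered protein variants arranged on an
#' insert x strategy grid: each record is one construct (a scaffold
#' carrying peptide insert `insert_id` placed by insertion strategy
#' `strategy_id`) with its amino-acid sequence and, optionally, a binary
#' solubility label (1 = soluble, 0 = insoluble).  The two grid axes are
#' the sampling strata used by [stratified_sample()].
#'
#' @param records `data.frame` with columns `construct_id` (unique
#'   character), `insert_id` (integer), `strategy_id` (integer),
#'   `sequence` (amino-acid string) and optionally `label` (0/1 or `NA`).
#' @param n_inserts,n_strategies Stratum counts; default: number of
#'   distinct ids present.
#' @param trim_n,trim_c Optional provenance: lengths of the constant N-
#'   and C-terminal flanks to omit from feature windows.
#' @return Object of class `construct_dataset`.
#' @seealso [read_constructs()], [generate_dataset()]
#' @export
construct_dataset <- function(records, n_inserts = NULL, n_strategies = NULL,
                              trim_n = NULL, trim_c = NULL) {
  need <- c("construct_id", "insert_id", "strategy_id", "sequence")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stopf("records lack column(s): %s", paste(miss, collapse = ", "))
  records$construct_id <- as.character(records$construct_id)
  if (anyDuplicated(records$construct_id))
    stopf("duplicate construct_id: %s",
          records$construct_id[duplicated(records$construct_id)][1L])
  key <- paste(records$insert_id, records$strategy_id)
  if (anyDuplicated(key))
    stopf("duplicate (insert_id, strategy_id) pair: %s",
          key[duplicated(key)][1L])
  if (!"label" %in% names(records)) records$label <- NA_integer_
  lab <- records$label
  if (!all(is.na(lab) | lab %in% c(0, 1)))
    stopf("labels must be 0, 1 or NA")
  structure(
    list(records = records,
         n_inserts = n_inserts %||% length(unique(records$insert_id)),
         n_strategies = n_strategies %||% length(unique(records$strategy_id)),
         trim_n = trim_n, trim_c = trim_c),
    class = "construct_dataset")
}

#' @export
print.construct_dataset <- function(x, ...) {
  cat(sprintf("<construct_dataset> %d constructs (%d inserts x %d strategies)\n",
              nrow(x$records), x$n_inserts, x$n_strategies))
  lab <- x$records$label
  if (all(!is.na(lab)))
    cat(sprintf("  f_sol = %.3f (%d soluble / %d)\n",
                mean(lab), sum(lab), length(lab)))
  if (!is.null(x$trim_n))
    cat(sprintf("  constant flanks: %d (N) / %d (C) residues\n",
                x$trim_n, x$trim_c))
  invisible(x)
}

#' @export
length.construct_dataset <- function(x) nrow(x$records)

# Subset a dataset by record index, preserving stratum counts.
subset_dataset <- function(ds, idx) {
  construct_dataset(ds$records[idx, , drop = FALSE],
                    n_inserts = ds$n_inserts,
                    n_strategies = ds$n_strategies,
                    trim_n = ds$trim_n, trim_c = ds$trim_c)
}

#' Fraction of soluble constructs
#'
#' @param ds A [construct_dataset()] with all labels present.
#' @return Fraction of records labelled 1.
#' @export
f_sol <- function(ds) {
  stopifnot(inherits(ds, "construct_dataset"))
  lab <- ds$records$label
  if (any(is.na(lab))) stopf("f_sol requires all labels present")
  mean(lab)
}

#' Read constructs from FASTA plus metadata CSV
#'
#' FASTA record names must match the `construct_id` column of the
#' metadata table (columns `construct_id`, `insert_id`, `strategy_id`,
#' optional `label`).  Every metadata row must have a sequence and vice
#' versa.
#'
#' @param fasta_path Amino-acid FASTA file.
#' @param meta_path Metadata CSV.
#' @return A [construct_dataset()] in metadata row order.
#' @export
read_constructs <- function(fasta_path, meta_path) {
  if (!file.exists(fasta_path)) stopf("FASTA file not found: %s", fasta_path)
  if (!file.exists(meta_path)) stopf("metadata file not found: %s", meta_path)
  fa <- seqinr::read.fasta(fasta_path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  seqs <- toupper(vapply(fa, function(x) as.character(x)[1L], character(1)))
  ids <- names(fa)
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1L])
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("construct_id", "insert_id", "strategy_id")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stopf("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  meta$construct_id <- as.character(meta$construct_id)
  unknown <- setdiff(meta$construct_id, ids)
  if (length(unknown))
    stopf("metadata id(s) absent from FASTA: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  orphan <- setdiff(ids, meta$construct_id)
  if (length(orphan))
    stopf("FASTA id(s) without metadata: %s",
          paste(utils::head(orphan, 5), collapse = ", "))
  if ("label" %in% names(meta)) {
    lab <- meta$label
    if (!all(is.na(lab) | lab %in% c(0, 1)))
      stopf("metadata labels must be 0, 1 or empty")
  }
  meta$sequence <- unname(seqs[meta$construct_id])
  construct_dataset(meta)
}

#' Write a construct dataset as FASTA plus metadata CSV
#'
#' Inverse of [read_constructs()]; used by the command-line `simulate`
#' step.
#'
#' @param ds A [construct_dataset()].
#' @param fasta_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_constructs <- function(ds, fasta_path, meta_path) {
  stopifnot(inherits(ds, "construct_dataset"))
  rec <- ds$records
  seqinr::write.fasta(as.list(rec$sequence), names = rec$construct_id,
                      file.out = fasta_path, nbchar = 60)
  utils::write.csv(rec[, c("construct_id", "insert_id", "strategy_id", "label")],
                   meta_path, row.names = FALSE)
  invisible(c(fasta = fasta_path, meta = meta_path))
}

# Residue count matrix over the feature window: n_records x 20.
# unknown_aa: "error" (default), "zero" (count ignored in feature sums),
# "skip" (residue dropped) -- zero and skip coincide for count sums.
window_counts <- function(seqs, trim_n, trim_c,
                          unknown_aa = c("error", "zero", "skip"),
                          ids = NULL) {
  unknown_aa <- match.arg(unknown_aa)
  n <- length(seqs)
  counts <- matrix(0L, n, 20L, dimnames = list(ids, AA_CODES))
  for (i in seq_len(n)) {
    chars <- split_residues(seqs[i])
    len <- length(chars)
    if (len < trim_n + trim_c + 1L)
      stopf("sequence %s: empty feature window (length %d, trims %d + %d)",
            ids[i] %||% i, len, trim_n, trim_c)
    win <- chars[(trim_n + 1L):(len - trim_c)]
    idx <- match(win, AA_CODES)
    if (anyNA(idx) && unknown_aa == "error")
      stopf("sequence %s: non-canonical residue '%s' in feature window",
            ids[i] %||% i, win[which(is.na(idx))[1L]])
    tab <- tabulate(idx[!is.na(idx)], nbins = 20L)
    counts[i, ] <- tab
  }
  counts
}

#' Summed-hydrophobicity feature of one sequence
#'
#' The feature value of a construct under a scale is the sum of the
#' scale's per-residue values over the variable window of the sequence,
#' i.e. residues `trim_n + 1` through `length - trim_c` (1-based,
#' inclusive).  The flanks are omitted because they are identical across
#' constructs and carry no class information.
#'
#' @param seq Amino-acid string.
#' @param scale A [hydro_scale()] (normalized and oriented for ensemble
#'   use; the charge baseline is used raw).
#' @param trim_n,trim_c Number of N-/C-terminal residues to omit
#'   (default 0).
#' @param unknown_aa Policy for residues without a scale value:
#'   `"error"` (default), `"zero"` or `"skip"` (both treat the residue
#'   as contributing nothing).
#' @return Single numeric feature value.
#' @examples
#' compute_feature("DEKR", charge_scale())  # charges cancel: 0
#' @export
compute_feature <- function(seq, scale, trim_n = 0L, trim_c = 0L,
                            unknown_aa = c("error", "zero", "skip")) {
  stopifnot(inherits(scale, "hydro_scale"))
  cnt <- window_counts(seq, as.integer(trim_n), as.integer(trim_c),
                       unknown_aa)
  as.numeric(cnt %*% scale$values)
}

#' Feature matrix of a dataset under a scale library
#'
#' Entry (i, j) is [compute_feature()] of record i under scale j; column
#' order equals library order.
#'
#' @param ds A [construct_dataset()].
#' @param lib A [scale_library()].
#' @param trim_n,trim_c Flank trims; default: the dataset's own trim
#'   provenance, else 73 and 71 (the constant-flank lengths of the
#'   chimeric HBcAg scaffold application).
#' @param unknown_aa See [compute_feature()].
#' @return Numeric matrix, rows named by `construct_id`, columns by scale
#'   id, with `trim_n`/`trim_c` attributes.
#' @export
build_feature_matrix <- function(ds, lib, trim_n = NULL, trim_c = NULL,
                                 unknown_aa = c("error", "zero", "skip")) {
  stopifnot(inherits(ds, "construct_dataset"), inherits(lib, "scale_library"))
  trim_n <- as.integer(trim_n %||% ds$trim_n %||% 73L)
  trim_c <- as.integer(trim_c %||% ds$trim_c %||% 71L)
  cnt <- window_counts(ds$records$sequence, trim_n, trim_c,
                       unknown_aa, ids = ds$records$construct_id)
  fm <- cnt %*% as.matrix(lib)
  structure(fm, trim_n = trim_n, trim_c = trim_c)
}

#' Lysine / arginine count ratio
#'
#' K/R is a charge-preserving contrast between the two basic residues;
#' it is used as a one-feature baseline classifier for solubility.
#'
#' @param seq Amino-acid string (or character vector of them).
#' @return Numeric count(K) / count(R), vectorized over `seq`.  A
#'   sequence without arginine has no defined ratio and raises an error.
#' @export
kr_ratio <- function(seq) {
  out <- vapply(seq, function(s) {
    chars <- split_residues(s)
    if (length(chars) == 0L) stopf("empty sequence")
    k <- sum(chars == "K")
    r <- sum(chars == "R")
    if (r == 0L)
      stopf("K/R ratio undefined: sequence contains no arginine")
    k / r
  }, numeric(1), USE.NAMES = FALSE)
  out
}
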