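# Shared constants and small internal helpers.

# Canonical one-letter amino-acid codes, fixed order used throughout:
# scale vectors, residue count matrices and the scale CSV interface.
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand one master seed into independent child seeds
#'
#' All repeated-randomization routines (Monte Carlo cross-validation, the
#' learning experiment) derive one child seed per fold/replicate from a
#' single user-facing seed, so that runs are bit-reproducible and
#' individual folds can be replayed in isolation.
#'
#' @param seed Integer master seed, or `NULL` for no seeding.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, or `NULL` when `seed` is `NULL`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Split a character scalar into single residues (upper-cased).
split_residues <- function(seq) {
  strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
}

is_binary_labels <- function(y) {
  is.numeric(y) && all(y %in% c(0, 1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
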