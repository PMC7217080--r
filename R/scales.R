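#' Hydrophobicity scale objects
#'
#' A hydrophobicity scale assigns one real value to each of the 20
#' canonical amino acids.  Scales are the elementary classifiers of the
#' ensemble: every scale yields one sequence feature (the summed
#' per-residue value over the variable window) and hence one decision
#' stump.  Before use in the ensemble, scales are centred to mean zero and
#' scaled to unit variance, and their sign is oriented so that aspartic
#' acid (D) is non-positive, i.e. larger values always mean "more
#' hydrophobic".
#'
#' @param id Short unique identifier.
#' @param values Numeric vector with one value per canonical amino acid.
#'   Must be named by the one-letter codes (any order); stored in
#'   canonical order A, R, N, D, C, Q, E, G, H, I, L, K, M, F, P, S, T,
#'   W, Y, V.
#' @param normalized Logical; `TRUE` once the scale has been centred and
#'   scaled to unit variance.
#' @return An object of class `hydro_scale`: a list with elements `id`,
#'   `values` (named numeric of length 20) and `normalized`.
#' @examples
#' s <- hydro_scale("toy", stats::setNames(seq(-1, 1, length.out = 20),
#'                  c("A","R","N","D","C","Q","E","G","H","I",
#'                    "L","K","M","F","P","S","T","W","Y","V")))
#' normalize_scale(s)
#' @export
hydro_scale <- function(id, values, normalized = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stopf("scale id must be a non-empty string")
  if (length(values) != 20L)
    stopf("scale '%s' must have exactly 20 values, got %d", id, length(values))
  if (is.null(names(values)) || !setequal(names(values), AA_CODES))
    stopf("scale '%s' values must be named by the 20 canonical amino acids", id)
  if (!is.numeric(values) || any(!is.finite(values)))
    stopf("scale '%s' contains non-finite values", id)
  structure(
    list(id = id,
         values = as.numeric(values[AA_CODES]) |> stats::setNames(AA_CODES),
         normalized = isTRUE(normalized)),
    class = "hydro_scale")
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat(sprintf("<hydro_scale> %s%s\n", x$id,
              if (x$normalized) " (normalized)" else ""))
  print(round(x$values, 3))
  invisible(x)
}

#' Ordered collection of hydrophobicity scales
#'
#' @param scales List of [hydro_scale()] objects.  Ids must be unique;
#'   list order is preserved and defines tie-breaking during feature
#'   selection.
#' @param provenance Optional character vector of free-text notes, one
#'   per scale (e.g. literature origin, reversed-scale flag).
#' @return Object of class `scale_library`.
#' @export
scale_library <- function(scales, provenance = NULL) {
  if (length(scales) == 0L) stopf("scale library must contain at least one scale")
  ok <- vapply(scales, inherits, logical(1), what = "hydro_scale")
  if (!all(ok)) stopf("all elements must be hydro_scale objects")
  ids <- vapply(scales, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stopf("duplicate scale id: %s", ids[duplicated(ids)][1L])
  if (is.null(provenance)) provenance <- rep("", length(scales))
  if (length(provenance) != length(scales))
    stopf("provenance must have one entry per scale")
  structure(list(scales = scales, ids = ids,
                 provenance = as.character(provenance)),
            class = "scale_library")
}

#' @export
length.scale_library <- function(x) length(x$scales)

#' @export
`[[.scale_library` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  x$scales[[i]]
}

#' @export
`[.scale_library` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  scale_library(x$scales[i], x$provenance[i])
}

#' @export
print.scale_library <- function(x, ...) {
  cat(sprintf("<scale_library> %d scales: %s\n", length(x),
              paste(utils::head(x$ids, 8), collapse = ", ")))
  if (length(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Matrix view of a scale library (20 amino acids x n scales)
#'
#' @param x A `scale_library`.
#' @param ... Unused.
#' @return Numeric matrix, rows named by amino acid, columns by scale id.
#' @export
as.matrix.scale_library <- function(x, ...) {
  m <- vapply(x$scales, `[[`, numeric(20), "values")
  dimnames(m) <- list(AA_CODES, x$ids)
  m
}

#' Read a hydrophobicity-scale table from CSV
#'
#' Expected layout: one scale per row; a `scale_id` column plus 20 numeric
#' columns headed by the one-letter amino-acid codes (any column order).
#' An optional logical/0-1 `reversed` column flags scales published with
#' inverted sign; the flag is honoured by [exclude_reversed_scales()].
#'
#' @param path Path to a UTF-8, comma-separated file with `.` decimals.
#' @return A [scale_library()] in file order, un-normalized.
#' @export
read_scale_table <- function(path) {
  if (!file.exists(path)) stopf("scale table not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"scale_id" %in% names(df))
    stopf("scale table %s lacks a 'scale_id' column", path)
  missing <- setdiff(AA_CODES, names(df))
  if (length(missing))
    stopf("scale table %s is missing amino-acid column(s): %s",
          path, paste(missing, collapse = ", "))
  for (aa in AA_CODES) {
    col <- df[[aa]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) | !grepl("^[-+0-9.eE]+$", col))[1L]
      stopf("non-numeric value in scale table %s, row %d, column %s",
            path, bad %||% 1L, aa)
    }
    if (any(is.na(col)))
      stopf("missing value in scale table %s, row %d, column %s",
            path, which(is.na(col))[1L], aa)
  }
  ids <- as.character(df$scale_id)
  if (anyDuplicated(ids))
    stopf("duplicate scale id in %s: %s", path, ids[duplicated(ids)][1L])
  rev_flag <- if ("reversed" %in% names(df)) as.logical(df$reversed) else rep(FALSE, nrow(df))
  scales <- lapply(seq_len(nrow(df)), function(i) {
    hydro_scale(ids[i], stats::setNames(as.numeric(df[i, AA_CODES]), AA_CODES))
  })
  scale_library(scales,
                provenance = ifelse(rev_flag, "reversed", ""))
}

#' Centre a scale and scale it to unit variance
#'
#' Uses the population variance convention (divisor 20): a scale is a
#' complete enumeration of the 20 residues, not a sample from a larger
#' population.
#'
#' @param s A [hydro_scale()].
#' @return The normalized scale (`normalized = TRUE`), same id.
#' @export
normalize_scale <- function(s) {
  stopifnot(inherits(s, "hydro_scale"))
  v <- s$values
  m <- mean(v)
  sd_pop <- sqrt(mean((v - m)^2))
  if (sd_pop == 0)
    stopf("scale '%s' is degenerate: all 20 values identical", s$id)
  hydro_scale(s$id, (v - m) / sd_pop, normalized = TRUE)
}

#' Orient a scale so that aspartic acid is non-positive
#'
#' Hydrophobicity scales are published with both sign conventions; after
#' orientation, negative always means hydrophilic.  If the value for D is
#' positive the whole scale is negated, otherwise it is returned
#' unchanged (idempotent).
#'
#' @param s A [hydro_scale()].
#' @return Oriented scale.
#' @export
orient_scale <- function(s) {
  stopifnot(inherits(s, "hydro_scale"))
  if (s$values[["D"]] > 0)
    s$values <- -s$values
  s
}

#' Normalize, orient and de-duplicate a scale library
#'
#' Applies [normalize_scale()] then [orient_scale()] to every scale, and
#' optionally drops reversed duplicates (see
#' [exclude_reversed_scales()]).
#'
#' @param lib A [scale_library()].
#' @param exclude_reversed Drop a scale when its exact negation is also
#'   present? Default `TRUE`.
#' @return Prepared `scale_library`.
#' @export
prepare_scales <- function(lib, exclude_reversed = TRUE) {
  stopifnot(inherits(lib, "scale_library"))
  scales <- lapply(lib$scales, function(s) orient_scale(normalize_scale(s)))
  out <- scale_library(scales, lib$provenance)
  if (exclude_reversed) out <- exclude_reversed_scales(out)
  out
}

#' Drop reversed duplicates from a scale library
#'
#' Two scales are considered a reversed pair when, after normalization,
#' they are exactly anti-correlated (Pearson r = -1 within `tol`).  Of
#' each pair only one scale is kept: the one not flagged `reversed` in
#' the input table, or (if neither or both are flagged) the one earlier
#' in library order.  Note that after sign orientation a reversed pair
#' collapses to exact duplicates, which are removed by the same rule.
#'
#' @param lib A [scale_library()] of normalized scales.
#' @param tol Tolerance on `|r + 1|` (or `|r - 1|` for oriented
#'   duplicates). Default `1e-9`.
#' @return Filtered library, original order preserved.
#' @export
exclude_reversed_scales <- function(lib, tol = 1e-9) {
  stopifnot(inherits(lib, "scale_library"))
  n <- length(lib)
  if (n < 2L) return(lib)
  m <- as.matrix(lib)
  # normalize columns for detection regardless of input state
  m <- scale(m, center = TRUE, scale = TRUE)
  drop <- logical(n)
  flagged <- lib$provenance == "reversed"
  for (i in seq_len(n - 1L)) {
    if (drop[i]) next
    for (j in seq(i + 1L, n)) {
      if (drop[j]) next
      r <- stats::cor(m[, i], m[, j])
      if (abs(r + 1) < tol || abs(r - 1) < tol) {
        # prefer dropping the flagged member; default: keep earlier
        if (flagged[i] && !flagged[j]) drop[i] <- TRUE else drop[j] <- TRUE
      }
    }
  }
  lib[which(!drop)]
}

#' The charge "scale" baseline
#'
#' Rates aspartic and glutamic acid -1, arginine and lysine +1 and all
#' other amino acids 0, so that the summed window feature is the net
#' charge of the region.  Used raw (un-normalized) as a baseline feature
#' against which the hydrophobicity ensemble is compared.
#'
#' @return A [hydro_scale()] with id `"CHARGE"`, `normalized = FALSE`.
#' @export
charge_scale <- function() {
  v <- stats::setNames(numeric(20), AA_CODES)
  v[c("D", "E")] <- -1
  v[c("R", "K")] <- 1
  hydro_scale("CHARGE", v, normalized = FALSE)
}

#' Bundled example scale library
#'
#' Ten well-known published hydrophobicity scales shipped with the
#' package as test fixtures and defaults for the synthetic-data pipeline
#' (Kyte-Doolittle, Hopp-Woods, Eisenberg consensus, Fauchere-Pliska,
#' Janin, Engelman GES, Rose, Black-Mould, Wimley-White interface,
#' Miyazawa-Jernigan).  This is a convenience set, not the full 91-scale
#' collection used in large solubility studies.
#'
#' @param prepare Normalize and orient the scales (default `TRUE`).
#' @return A [scale_library()].
#' @export
example_scale_library <- function(prepare = TRUE) {
  path <- system.file("extdata", "example_scales.csv", package = "sevc",
                      mustWork = TRUE)
  lib <- read_scale_table(path)
  if (prepare) prepare_scales(lib) else lib
}

#' Per-amino-acid median and MAD across a scale library
#'
#' Summarizes the consensus hydrophobicity of each residue over all
#' scales in a library: the median value and the (unscaled) median
#' absolute deviation.  Used to ask where an individual scale deviates
#' from the population of scales.
#'
#' @param lib A [scale_library()]; scales should be normalized and
#'   oriented for the summary to be meaningful.
#' @return `data.frame` with columns `aa`, `median`, `mad` (20 rows,
#'   canonical order).
#' @export
scale_profile_stats <- function(lib) {
  stopifnot(inherits(lib, "scale_library"))
  if (length(lib) == 0L) stopf("empty scale library")
  m <- as.matrix(lib)
  med <- apply(m, 1L, stats::median)
  mad_ <- apply(m, 1L, function(r) stats::median(abs(r - stats::median(r))))
  data.frame(aa = AA_CODES, median = as.numeric(med), mad = as.numeric(mad_),
             stringsAsFactors = FALSE)
}

#' Principal-component variance-explained ratios of a scale library
#'
#' Treats the 20 amino acids as observations and the scales as variables,
#' and eigen-decomposes the covariance matrix (classical PCA).  A large
#' first ratio means the scales are strongly collinear, i.e. the library
#' carries much less independent information than its size suggests.
#'
#' @param lib A [scale_library()] of at least two normalized scales.
#' @return Numeric vector of variance-explained ratios, descending,
#'   summing to 1.
#' @export
pca_variance_explained <- function(lib) {
  stopifnot(inherits(lib, "scale_library"))
  if (length(lib) < 2L)
    stopf("PCA requires at least two scales, got %d", length(lib))
  m <- as.matrix(lib)           # 20 observations x n_scales variables
  pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  ev / sum(ev)
}
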