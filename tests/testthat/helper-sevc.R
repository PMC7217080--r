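# Shared fixtures and independent oracles for the test suite.

aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

named20 <- function(x) stats::setNames(x, aa20)

# small deterministic scale for hand-checked feature sums
toy_scale <- function(id = "TOY", values = named20(seq(-1, 0.9, by = 0.1))) {
  hydro_scale(id, values)
}

# Independent decision-stump oracle: exhaustive enumeration of all
# midpoints between consecutive distinct sorted values, strict-improvement
# scan in ascending threshold order (keeps the smallest optimal threshold).
brute_stump <- function(x, y) {
  n <- length(x)
  g <- function(v) {
    if (length(v) == 0L) return(0)
    p1 <- mean(v == 1)
    1 - p1^2 - (1 - p1)^2
  }
  best <- list(gini = g(y), threshold = NA_real_, leaf_only = TRUE)
  xs <- sort(unique(x))
  if (length(xs) >= 2L) {
    for (i in seq_len(length(xs) - 1L)) {
      thr <- (xs[i] + xs[i + 1L]) / 2
      L <- y[x < thr]; R <- y[x >= thr]
      wg <- (length(L) * g(L) + length(R) * g(R)) / n
      if (wg < best$gini - 1e-12)
        best <- list(gini = wg, threshold = thr, leaf_only = FALSE)
    }
  }
  best
}

# weighted Gini of a fitted stump recomputed from data (for comparisons)
stump_wgini <- function(st, x, y) {
  g <- function(v) {
    if (length(v) == 0L) return(0)
    p1 <- mean(v == 1)
    1 - p1^2 - (1 - p1)^2
  }
  if (st$is_leaf_only) return(g(y))
  L <- y[x < st$threshold]; R <- y[x >= st$threshold]
  (length(L) * g(L) + length(R) * g(R)) / length(y)
}

# direct Eq.-style MCC used as an oracle against the package's mcc()
mcc_direct <- function(tp, tn, fp, fn) {
  (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
}

# tiny labelled dataset with fully controlled sequences (trim 0/0)
manual_dataset <- function(seqs, labels) {
  construct_dataset(
    data.frame(construct_id = sprintf("c%02d", seq_along(seqs)),
               insert_id = seq_along(seqs), strategy_id = 1L,
               sequence = seqs, label = labels,
               stringsAsFactors = FALSE),
    trim_n = 0L, trim_c = 0L)
}

# small synthetic grid used by several evaluation tests
small_sim <- function(seed = 11, ...) {
  generate_dataset(synthetic_config(n_inserts = 12L, n_strategies = 4L,
                                    seed = seed, ...))
}
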