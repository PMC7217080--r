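#' Stratified sampling of constructs with per-stratum caps
#'
#' Draws `n_train` constructs without replacement while keeping both
#' strata (inserts and strategies) evenly represented: a given insert may
#' occur at most `ceiling(n_train / n_inserts)` times and a given
#' strategy at most `ceiling(n_train / n_strategies)` times.  As soon as
#' a stratum reaches its cap, all remaining constructs of that stratum
#' become unavailable to further random selection.
#'
#' @param ds A [construct_dataset()].
#' @param n_train Number of constructs to draw (`<= nrow`).
#' @param seed Optional integer seed for reproducibility.
#' @return List with elements `train` and `rest` (complement), both
#'   [construct_dataset()]s, plus the caps used.
#' @export
stratified_sample <- function(ds, n_train, seed = NULL) {
  stopifnot(inherits(ds, "construct_dataset"))
  n <- nrow(ds$records)
  n_train <- as.integer(n_train)
  if (n_train < 1L || n_train > n)
    stopf("n_train must be in 1..%d", n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cap_insert <- ceiling(n_train / ds$n_inserts)
  cap_strategy <- ceiling(n_train / ds$n_strategies)
  ins <- as.character(ds$records$insert_id)
  str <- as.character(ds$records$strategy_id)
  cnt_i <- integer(0); cnt_s <- integer(0)
  pool <- seq_len(n)
  chosen <- integer(0)
  for (draw in seq_len(n_train)) {
    if (length(pool) == 0L)
      stopf("stratified sampling infeasible: caps exhausted the pool after %d of %d draws",
            length(chosen), n_train)
    pick <- pool[sample.int(length(pool), 1L)]
    chosen <- c(chosen, pick)
    pool <- pool[pool != pick]
    i_id <- ins[pick]; s_id <- str[pick]
    cnt_i[i_id] <- (if (i_id %in% names(cnt_i)) cnt_i[[i_id]] else 0L) + 1L
    cnt_s[s_id] <- (if (s_id %in% names(cnt_s)) cnt_s[[s_id]] else 0L) + 1L
    if (cnt_i[[i_id]] >= cap_insert) pool <- pool[ins[pool] != i_id]
    if (cnt_s[[s_id]] >= cap_strategy) pool <- pool[str[pool] != s_id]
  }
  chosen <- sort(chosen)
  list(train = subset_dataset(ds, chosen),
       rest = subset_dataset(ds, setdiff(seq_len(n), chosen)),
       cap_insert = cap_insert, cap_strategy = cap_strategy)
}

#' Monte Carlo cross-validation of the sEVC
#'
#' Repeated random 50/50 (by default) splitting of a labelled dataset:
#' in each of `n_folds` folds, `floor(train_frac * n)` constructs are
#' drawn without replacement for training, the stumps are fit and
#' feature selection performed on that half only, and the remaining
#' constructs are predicted for every candidate ensemble size `k`.
#' Folds whose MCC is undefined (a zero denominator factor) are recorded
#' as missing for that fold/k and excluded from the median, with the
#' exclusion count reported.
#'
#' @param ds Labelled [construct_dataset()] (>= 4 records).
#' @param lib A [scale_library()] of prepared scales.
#' @param n_folds Number of Monte Carlo folds (default 100).
#' @param train_frac Training fraction per fold (default 0.5).
#' @param k_range Ensemble sizes to screen; default `1:length(lib)`.
#' @param trim_n,trim_c Feature-window trims (default: dataset
#'   provenance).
#' @param seed Master seed; per-fold child seeds are derived from it.
#' @param vote `"soft"` or `"hard"` voting.
#' @return Object of class `sevc_cv`: per-fold MCC matrix
#'   (`n_folds x length(k_range)`), per-k `median` and `mad`, exclusion
#'   counts and the derived fold seeds.
#' @export
mc_cv <- function(ds, lib, n_folds = 100L, train_frac = 0.5,
                  k_range = NULL, trim_n = NULL, trim_c = NULL,
                  seed = NULL, vote = "soft") {
  stopifnot(inherits(ds, "construct_dataset"))
  y <- ds$records$label
  if (any(is.na(y))) stopf("cross-validation requires labels for every record")
  n <- length(y)
  if (n < 4L) stopf("need at least 4 labelled records")
  fm <- build_feature_matrix(ds, lib, trim_n = trim_n, trim_c = trim_c)
  k_range <- as.integer(k_range %||% seq_len(ncol(fm)))
  if (any(k_range < 1L) || any(k_range > ncol(fm)))
    stopf("k_range must lie in 1..%d", ncol(fm))
  n_tr <- floor(train_frac * n)
  if (n_tr < 2L || n_tr >= n) stopf("train_frac leaves too few records")
  fold_seeds <- derive_seeds(seed, n_folds)
  m <- matrix(NA_real_, n_folds, length(k_range),
              dimnames = list(NULL, paste0("k", k_range)))
  for (f in seq_len(n_folds)) {
    if (!is.null(fold_seeds)) set.seed(fold_seeds[f])
    idx <- sample.int(n, n_tr)
    fit <- sevc(fm[idx, , drop = FALSE], y[idx])
    cls <- cum_vote_classes(fit, fm[-idx, , drop = FALSE], k_range,
                            vote = vote)$class
    m[f, ] <- vapply(seq_along(k_range), function(j)
      mcc_from_labels(y[-idx], cls[, j]), numeric(1))
  }
  med <- apply(m, 2L, function(v) median_mad(v)[["median"]])
  mad_ <- apply(m, 2L, function(v) median_mad(v)[["mad"]])
  structure(list(mcc = m, k = k_range, median = med, mad = mad_,
                 n_excluded = colSums(is.na(m)),
                 n_folds = n_folds, n_train = n_tr,
                 fold_seeds = fold_seeds, vote = vote),
            class = "sevc_cv")
}

#' @export
print.sevc_cv <- function(x, ...) {
  best <- which.max(x$median)
  cat(sprintf("<sevc_cv> %d folds, train size %d, k in %d..%d\n",
              x$n_folds, x$n_train, min(x$k), max(x$k)))
  cat(sprintf("  best median MCC %.3f (MAD %.3f) at k = %d; %d fold/k cells undefined\n",
              x$median[best], x$mad[best], x$k[best], sum(x$n_excluded)))
  invisible(x)
}

#' @export
plot.sevc_cv <- function(x, ...) {
  graphics::plot(x$k, x$median, type = "o", pch = 16, ylim = c(-1, 1),
                 xlab = "included decision trees (k)",
                 ylab = "validation MCC (median)", ...)
  graphics::polygon(c(x$k, rev(x$k)),
                    c(x$median - x$mad, rev(x$median + x$mad)),
                    border = NA, col = grDevices::adjustcolor("orange", 0.3))
  graphics::lines(x$k, x$median, type = "o", pch = 16)
  invisible(x)
}

# classification group of each (truth, prediction) pair
class_group <- function(truth, predicted) {
  g <- character(length(truth))
  g[truth == 1 & predicted == 1] <- "TP"
  g[truth == 0 & predicted == 0] <- "TN"
  g[truth == 0 & predicted == 1] <- "FP"
  g[truth == 1 & predicted == 0] <- "FN"
  g
}

GROUPS <- c("TP", "TN", "FP", "FN")

# accumulate strategy x group counts for one prediction set
tally_strategy_groups <- function(counts, strategies, truth, predicted) {
  g <- class_group(truth, predicted)
  t2 <- table(factor(strategies, rownames(counts)), factor(g, GROUPS))
  counts + unclass(t2)
}

#' Learning experiment over training size and ensemble size
#'
#' Explores the model design space on a fixed training pool and a fixed,
#' disjoint external test set.  For every training size and repetition,
#' a training set is drawn from the pool randomly *without*
#' stratification, stumps are fit and ranked on that draw, and the
#' ensemble is evaluated for every ensemble size `k` on both the
#' training draw and the external test set.  Median and MAD over the
#' repetitions summarize each (size, k) cell.  Per-strategy
#' classification-group counts are accumulated over all models and `k`
#' for [misclassification_frequency()].
#'
#' @param pool Labelled training-pool [construct_dataset()].
#' @param test Labelled external-test [construct_dataset()]; must be
#'   disjoint from `pool`.
#' @param lib A [scale_library()].
#' @param sizes Training sizes; default: 5% to 95% of the pool in 5%
#'   steps plus the full pool as the final size (19 sizes).
#' @param reps Repetitions per size (default 10).
#' @param k_values Ensemble sizes to screen; default `1:length(lib)`.
#' @param trim_n,trim_c Feature-window trims (default: pool provenance).
#' @param seed Master seed (per-model child seeds derived from it).
#' @return Object of class `sevc_learning`: MCC arrays
#'   `sizes x reps x k` for training and test, per-cell `median`/`mad`
#'   matrices (recomputable from the stored replicates), and strategy x
#'   group count matrices.
#' @export
learning_experiment <- function(pool, test, lib, sizes = NULL, reps = 10L,
                                k_values = NULL, trim_n = NULL, trim_c = NULL,
                                seed = NULL) {
  stopifnot(inherits(pool, "construct_dataset"),
            inherits(test, "construct_dataset"))
  if (length(intersect(pool$records$construct_id, test$records$construct_id)))
    stopf("training pool and external test set overlap")
  y_pool <- pool$records$label
  y_test <- test$records$label
  if (any(is.na(y_pool)) || any(is.na(y_test)))
    stopf("learning experiment requires labels on pool and test set")
  n <- length(y_pool)
  if (is.null(sizes)) {
    sizes <- round(0.05 * seq_len(19L) * n)
    sizes[19L] <- n                     # printed-endpoint convention
  }
  sizes <- as.integer(sizes)
  if (any(sizes < 2L) || any(sizes > n)) stopf("sizes must lie in 2..%d", n)
  fm_pool <- build_feature_matrix(pool, lib, trim_n = trim_n, trim_c = trim_c)
  fm_test <- build_feature_matrix(test, lib, trim_n = trim_n, trim_c = trim_c)
  k_values <- as.integer(k_values %||% seq_len(ncol(fm_pool)))
  n_k <- length(k_values)
  model_seeds <- derive_seeds(seed, length(sizes) * reps)
  dn <- list(paste0("n", sizes), NULL, paste0("k", k_values))
  train_mcc <- array(NA_real_, c(length(sizes), reps, n_k), dimnames = dn)
  test_mcc <- array(NA_real_, c(length(sizes), reps, n_k), dimnames = dn)
  strat_levels <- sort(unique(c(pool$records$strategy_id,
                                test$records$strategy_id)))
  counts_train <- matrix(0, length(strat_levels), 4L,
                         dimnames = list(strat_levels, GROUPS))
  counts_test <- counts_train
  m_idx <- 0L
  for (si in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      m_idx <- m_idx + 1L
      if (!is.null(model_seeds)) set.seed(model_seeds[m_idx])
      idx <- sample.int(n, sizes[si])
      fit <- sevc(fm_pool[idx, , drop = FALSE], y_pool[idx])
      cls_tr <- cum_vote_classes(fit, fm_pool[idx, , drop = FALSE],
                                 k_values)$class
      cls_te <- cum_vote_classes(fit, fm_test, k_values)$class
      for (j in seq_len(n_k)) {
        train_mcc[si, r, j] <- mcc_from_labels(y_pool[idx], cls_tr[, j])
        test_mcc[si, r, j] <- mcc_from_labels(y_test, cls_te[, j])
        counts_train <- tally_strategy_groups(
          counts_train, pool$records$strategy_id[idx], y_pool[idx], cls_tr[, j])
        counts_test <- tally_strategy_groups(
          counts_test, test$records$strategy_id, y_test, cls_te[, j])
      }
    }
  }
  cell_stat <- function(a, what) {
    apply(a, c(1L, 3L), function(v)
      if (all(is.na(v))) NA_real_ else median_mad(v)[[what]])
  }
  structure(list(sizes = sizes, reps = reps, k = k_values,
                 train_mcc = train_mcc, test_mcc = test_mcc,
                 train_median = cell_stat(train_mcc, "median"),
                 train_mad = cell_stat(train_mcc, "mad"),
                 test_median = cell_stat(test_mcc, "median"),
                 test_mad = cell_stat(test_mcc, "mad"),
                 counts_train = counts_train, counts_test = counts_test,
                 model_seeds = model_seeds),
            class = "sevc_learning")
}

#' @export
print.sevc_learning <- function(x, ...) {
  cat(sprintf("<sevc_learning> %d sizes x %d k-values x %d reps (%d models)\n",
              length(x$sizes), length(x$k), x$reps,
              length(x$sizes) * x$reps))
  best <- arrayInd(which.max(x$test_median), dim(x$test_median))
  cat(sprintf("  best median test MCC %.3f at n_train = %d, k = %d\n",
              max(x$test_median, na.rm = TRUE),
              x$sizes[best[1L]], x$k[best[2L]]))
  invisible(x)
}

#' @export
plot.sevc_learning <- function(x, which = c("test", "train"), ...) {
  which <- match.arg(which)
  m <- if (which == "test") x$test_median else x$train_median
  graphics::image(x$k, x$sizes, t(m), xlab = "included decision trees (k)",
                  ylab = "training set size",
                  main = sprintf("median %s MCC", which), ...)
  invisible(x)
}

#' Per-strategy relative frequency of classification groups
#'
#' For each stratum (insertion strategy) the occurrences in the four
#' classification groups TP/TN/FP/FN are summed over all models and then
#' normalized by the stratum's total occurrence over all groups and
#' models, so each row sums to 1.  A strategy whose FP (or FN) share
#' systematically exceeds its FN (FP) share is one whose solubility the
#' ensemble over- (under-) estimates.
#'
#' @param x Either a `sevc_learning` result, a strategy-by-group count
#'   matrix (columns TP, TN, FP, FN), or a `data.frame` of per-model
#'   predictions with columns `construct_id`, `truth`, `predicted`
#'   (a `model` column may repeat constructs across models).
#' @param ds For the `data.frame` method: the [construct_dataset()]
#'   supplying each construct's strategy.
#' @param which For `sevc_learning` input: `"test"` (default) or
#'   `"train"` counts.
#' @return Object of class `misclass_freq`: strategy x group matrix of
#'   relative frequencies (rows sum to 1), with the raw counts as
#'   attribute `counts`.
#' @export
misclassification_frequency <- function(x, ds = NULL, which = "test") {
  counts <-
    if (inherits(x, "sevc_learning")) {
      if (identical(which, "train")) x$counts_train else x$counts_test
    } else if (is.matrix(x)) {
      if (!all(GROUPS %in% colnames(x)))
        stopf("count matrix must have columns TP, TN, FP, FN")
      x[, GROUPS, drop = FALSE]
    } else if (is.data.frame(x)) {
      if (is.null(ds)) stopf("ds is required to map constructs to strategies")
      need <- c("construct_id", "truth", "predicted")
      if (!all(need %in% names(x)))
        stopf("prediction data.frame needs columns %s",
              paste(need, collapse = ", "))
      strat <- ds$records$strategy_id[
        match(x$construct_id, ds$records$construct_id)]
      if (anyNA(strat)) stopf("prediction contains unknown construct_id")
      lev <- sort(unique(ds$records$strategy_id))
      m <- matrix(0, length(lev), 4L, dimnames = list(lev, GROUPS))
      tally_strategy_groups(m, strat, x$truth, x$predicted)
    } else stopf("unsupported input to misclassification_frequency")
  tot <- rowSums(counts)
  if (any(tot == 0))
    stopf("strategy %s occurs in no classification group",
          rownames(counts)[tot == 0][1L])
  structure(sweep(counts, 1L, tot, "/"), counts = counts,
            class = c("misclass_freq", "matrix"))
}

#' @export
print.misclass_freq <- function(x, ...) {
  cat("relative frequency of classification groups by strategy:\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' One-stump baselines: K/R ratio and net window charge
#'
#' `kr_baseline()` fits a single decision stump on the lysine/arginine
#' count ratio of the full sequence; `charge_baseline()` fits one on the
#' summed net charge (D, E = -1; K, R = +1) of the feature window.  Both
#' report the training-set confusion matrix, accuracy and MCC, and serve
#' as simple reference classifiers for the hydrophobicity ensemble.
#'
#' @param ds Labelled [construct_dataset()].
#' @return Object of class `sevc_baseline`: list with `stump`,
#'   `confusion`, `accuracy`, `mcc` (NA when undefined) and `feature`.
#' @export
kr_baseline <- function(ds) {
  stopifnot(inherits(ds, "construct_dataset"))
  y <- ds$records$label
  if (any(is.na(y))) stopf("baseline requires labels")
  x <- kr_ratio(ds$records$sequence)
  baseline_from_feature(x, y, "KR_RATIO")
}

#' @rdname kr_baseline
#' @param trim_n,trim_c Feature-window trims (default: dataset
#'   provenance).
#' @export
charge_baseline <- function(ds, trim_n = NULL, trim_c = NULL) {
  stopifnot(inherits(ds, "construct_dataset"))
  y <- ds$records$label
  if (any(is.na(y))) stopf("baseline requires labels")
  trim_n <- as.integer(trim_n %||% ds$trim_n %||% 73L)
  trim_c <- as.integer(trim_c %||% ds$trim_c %||% 71L)
  x <- vapply(ds$records$sequence, compute_feature, numeric(1),
              scale = charge_scale(), trim_n = trim_n, trim_c = trim_c,
              USE.NAMES = FALSE)
  baseline_from_feature(x, y, "CHARGE")
}

baseline_from_feature <- function(x, y, id) {
  st <- fit_stump(x, y, scale_id = id)
  pred <- predict(st, x)$class
  cm <- confusion_matrix(y, pred)
  structure(list(stump = st, confusion = cm,
                 accuracy = accuracy(cm), mcc = mcc_or_na(cm),
                 feature = x),
            class = "sevc_baseline")
}

#' @export
print.sevc_baseline <- function(x, ...) {
  print(x$stump)
  cat(sprintf("baseline accuracy %.3f, MCC %s\n", x$accuracy,
              if (is.na(x$mcc)) "undefined" else sprintf("%.3f", x$mcc)))
  invisible(x)
}
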