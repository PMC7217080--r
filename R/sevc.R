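#' Fit a soft ensemble vote classifier (sEVC)
#'
#' The sEVC is an ensemble of decision stumps, one per hydrophobicity
#' scale.  Each stump is fit on its scale's summed-hydrophobicity
#' feature; the embedded feature-selection step then ranks stumps by
#' their feature importance, defined as the stump's accuracy on the
#' training set, in descending order (ties keep library/column order,
#' which makes the fit deterministic).  Prediction with ensemble size
#' `k` sums, over the `k` most important stumps, each stump's child-node
#' probability into the score of its decided class; the class with the
#' larger score wins (tie: class 0).
#'
#' @param x Numeric feature matrix (constructs x scales), e.g. from
#'   [build_feature_matrix()]; column names identify the scales.
#' @param y Binary labels (0/1), one per row.
#' @param k Default ensemble size used by [predict.sevc()]; defaults to
#'   the number of scales.
#' @return Object of class `sevc`: list with `stumps` (importance-sorted
#'   [fit_stump()] objects), `importance` (their training accuracies,
#'   non-increasing), `scale_ids` (sorted order), `k`, `n_train` and the
#'   feature-window provenance `trim_n`/`trim_c` when `x` carries it.
#' @examples
#' lib <- example_scale_library()
#' sim <- generate_dataset(synthetic_config(n_inserts = 8, n_strategies = 3,
#'                                          seed = 1))
#' fm <- build_feature_matrix(sim$dataset, lib)
#' fit <- sevc(fm, sim$dataset$records$label, k = 3)
#' fit
#' @export
sevc <- function(x, y, k = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("scale", seq_len(ncol(x)))
  if (nrow(x) != length(y)) stopf("nrow(x) and length(y) differ")
  if (any(is.na(y))) stopf("ensemble training requires labels for every row")
  if (!is_binary_labels(y)) stopf("labels must be 0/1")
  stumps <- lapply(seq_len(ncol(x)), function(j)
    fit_stump(x[, j], y, scale_id = colnames(x)[j]))
  importance <- vapply(stumps, `[[`, numeric(1), "training_accuracy")
  ord <- order(-importance)               # stable: ties keep column order
  k <- as.integer(k %||% ncol(x))
  if (k < 1L || k > ncol(x)) stopf("k must be in 1..%d", ncol(x))
  structure(
    list(stumps = stumps[ord],
         importance = importance[ord],
         scale_ids = colnames(x)[ord],
         k = k, n_train = nrow(x),
         trim_n = attr(x, "trim_n"), trim_c = attr(x, "trim_c")),
    class = "sevc")
}

#' @export
print.sevc <- function(x, ...) {
  cat(sprintf("<sevc> %d stumps, default k = %d, fit on %d constructs\n",
              length(x$stumps), x$k, x$n_train))
  cat(sprintf("  top scales: %s\n",
              paste(utils::head(x$scale_ids, 5), collapse = ", ")))
  cat(sprintf("  importance range: %.3f .. %.3f\n",
              max(x$importance), min(x$importance)))
  invisible(x)
}

#' Summarize an sEVC fit
#'
#' @param object A [sevc()] model.
#' @param ... Unused.
#' @return `data.frame` with one row per stump in selection order:
#'   `rank` (min-rank; tied importances share the smallest rank),
#'   `scale_id`, `importance`, `threshold`, child classes and
#'   probabilities.
#' @export
summary.sevc <- function(object, ...) {
  imp <- object$importance
  out <- data.frame(
    rank = rank(-imp, ties.method = "min"),
    scale_id = object$scale_ids,
    importance = imp,
    threshold = vapply(object$stumps, `[[`, numeric(1), "threshold"),
    left_class = vapply(object$stumps, `[[`, numeric(1), "left_class"),
    right_class = vapply(object$stumps, `[[`, numeric(1), "right_class"),
    left_prob = vapply(object$stumps, `[[`, numeric(1), "left_prob"),
    right_prob = vapply(object$stumps, `[[`, numeric(1), "right_prob"),
    leaf_only = vapply(object$stumps, `[[`, logical(1), "is_leaf_only"),
    stringsAsFactors = FALSE)
  class(out) <- c("summary.sevc", class(out))
  out
}

#' Feature importances of an sEVC fit
#'
#' @param object A [sevc()] model.
#' @param ... Unused.
#' @return Named numeric vector of training-set accuracies, in selection
#'   (descending) order.
#' @export
coef.sevc <- function(object, ...) {
  stats::setNames(object$importance, object$scale_ids)
}

# Per-stump vote matrices for newdata: list of n x k matrices
# (decided class and its probability), in selection order.
stump_votes <- function(object, newdata, k) {
  newdata <- as.matrix(newdata)
  ids <- object$scale_ids[seq_len(k)]
  missing <- setdiff(ids, colnames(newdata))
  if (length(missing))
    stopf("feature matrix lacks scale(s): %s", paste(missing, collapse = ", "))
  n <- nrow(newdata)
  cls <- matrix(0L, n, k)
  prb <- matrix(0, n, k)
  for (j in seq_len(k)) {
    p <- predict(object$stumps[[j]], newdata[, ids[j]])
    cls[, j] <- p$class
    prb[, j] <- p$prob
  }
  list(class = cls, prob = prb)
}

# Cumulative soft/hard-vote classes for every k in k_values (vector),
# returned as an n x length(k_values) integer matrix.  Shared by
# cross-validation and the learning experiment so that screening all
# ensemble sizes costs one pass.
cum_vote_classes <- function(object, newdata, k_values,
                             vote = c("soft", "hard")) {
  vote <- match.arg(vote)
  k_max <- max(k_values)
  v <- stump_votes(object, newdata, k_max)
  w <- if (vote == "hard") matrix(1, nrow(v$prob), ncol(v$prob)) else v$prob
  row_cumsum <- function(m) {
    if (ncol(m) == 1L) m
    else matrix(t(apply(m, 1L, cumsum)), nrow = nrow(m))
  }
  s1 <- row_cumsum(w * (v$class == 1L))
  s0 <- row_cumsum(w * (v$class == 0L))
  cls <- (s1[, k_values, drop = FALSE] > s0[, k_values, drop = FALSE])
  storage.mode(cls) <- "integer"         # tie (s1 == s0) -> class 0
  list(class = cls, score1 = s1[, k_values, drop = FALSE],
       score0 = s0[, k_values, drop = FALSE])
}

#' Predict construct solubility with an sEVC
#'
#' @param object A [sevc()] model.
#' @param newdata Feature matrix with columns named by scale id (extra
#'   columns are ignored; all scales used by the first `k` stumps must be
#'   present).
#' @param k Ensemble size (number of most-important stumps included);
#'   default `object$k`.
#' @param vote `"soft"` (each stump contributes its child probability to
#'   its decided class) or `"hard"` (every vote counts 1).
#' @param ... Unused.
#' @return `data.frame` with columns `class` (0/1; score tie gives 0),
#'   `score0` and `score1` (summed probability mass per class; each is at
#'   most `k`).
#' @export
predict.sevc <- function(object, newdata, k = object$k,
                         vote = c("soft", "hard"), ...) {
  k <- as.integer(k)
  if (k < 1L || k > length(object$stumps))
    stopf("k must be in 1..%d", length(object$stumps))
  cv <- cum_vote_classes(object, newdata, k, vote = match.arg(vote))
  data.frame(class = as.integer(cv$class[, 1L]),
             score0 = as.numeric(cv$score0[, 1L]),
             score1 = as.numeric(cv$score1[, 1L]))
}

#' Soft vote of an ensemble on one feature vector
#'
#' @param model A [sevc()] model.
#' @param features Named numeric vector of feature values (names = scale
#'   ids) for one construct.
#' @param k Ensemble size.
#' @return List with `class`, `score0`, `score1`.
#' @export
soft_vote <- function(model, features, k = model$k) {
  m <- matrix(features, 1L, dimnames = list(NULL, names(features)))
  p <- predict(model, m, k = k, vote = "soft")
  list(class = p$class, score0 = p$score0, score1 = p$score1)
}

#' Hard (majority) vote of an ensemble on one feature vector
#'
#' Equivalent to [soft_vote()] with every probability replaced by 1; a
#' tied vote returns class 0.
#'
#' @inheritParams soft_vote
#' @return Predicted class (0/1).
#' @export
hard_vote <- function(model, features, k = model$k) {
  m <- matrix(features, 1L, dimnames = list(NULL, names(features)))
  predict(model, m, k = k, vote = "hard")$class
}

#' Row-wise ensemble prediction of a feature matrix
#'
#' Thin wrapper over [predict.sevc()] kept for symmetry with the
#' one-observation [soft_vote()].
#'
#' @inheritParams predict.sevc
#' @param fm Feature matrix (constructs x scales).
#' @param model A [sevc()] model.
#' @return See [predict.sevc()].
#' @export
predict_dataset <- function(model, fm, k = model$k) {
  predict(model, fm, k = k)
}

#' Serialize an sEVC model to JSON
#'
#' The file stores the ordered stump list with importances, the default
#' ensemble size, the feature-window trims and (optionally) the
#' normalized scale values, so that `predict` can be reproduced from the
#' file alone.
#'
#' @param model A [sevc()] model.
#' @param path Output path.
#' @param lib Optional [scale_library()] whose values are embedded.
#' @return Invisibly, `path`.
#' @export
write_sevc_json <- function(model, path, lib = NULL) {
  stopifnot(inherits(model, "sevc"))
  stumps <- lapply(model$stumps, function(s) s[c(
    "scale_id", "threshold", "left_class", "right_class",
    "left_prob", "right_prob", "is_leaf_only", "training_accuracy", "n")])
  obj <- list(format = "sevc-model", version = 1L,
              k = model$k, n_train = model$n_train,
              trim_n = model$trim_n, trim_c = model$trim_c,
              importance = model$importance,
              stumps = stumps)
  if (!is.null(lib)) {
    obj$scales <- lapply(lib$scales, function(s)
      list(id = s$id, values = as.list(s$values),
           normalized = s$normalized))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Deserialize an sEVC model from JSON
#'
#' @param path File written by [write_sevc_json()].
#' @return List with elements `model` (the [sevc()] object) and `lib`
#'   (the embedded [scale_library()], or `NULL`).
#' @export
read_sevc_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "sevc-model"))
    stopf("%s is not an sevc model file", path)
  stumps <- lapply(obj$stumps, function(s) {
    structure(list(scale_id = s$scale_id,
                   threshold = if (is.null(s$threshold)) NA_real_ else as.numeric(s$threshold),
                   left_class = as.integer(s$left_class),
                   right_class = as.integer(s$right_class),
                   left_prob = as.numeric(s$left_prob),
                   right_prob = as.numeric(s$right_prob),
                   is_leaf_only = isTRUE(s$is_leaf_only),
                   training_accuracy = as.numeric(s$training_accuracy),
                   n = as.integer(s$n)),
              class = "decision_stump")
  })
  model <- structure(
    list(stumps = stumps,
         importance = as.numeric(unlist(obj$importance)),
         scale_ids = vapply(stumps, `[[`, character(1), "scale_id"),
         k = as.integer(obj$k), n_train = as.integer(obj$n_train),
         trim_n = if (is.null(obj$trim_n)) NULL else as.integer(obj$trim_n),
         trim_c = if (is.null(obj$trim_c)) NULL else as.integer(obj$trim_c)),
    class = "sevc")
  lib <- NULL
  if (!is.null(obj$scales)) {
    scales <- lapply(obj$scales, function(s)
      hydro_scale(s$id, unlist(s$values), normalized = isTRUE(s$normalized)))
    lib <- scale_library(scales)
  }
  list(model = model, lib = lib)
}
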