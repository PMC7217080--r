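#' Fit a decision stump (one-level tree) on a single feature
#'
#' Induces a one-split binary tree by minimizing the weighted Gini
#' diversity index
#' \deqn{G = \sum_{child} \frac{n_{child}}{n}\,(1 - p_0^2 - p_1^2)}
#' over candidate thresholds placed at the midpoints between consecutive
#' distinct sorted feature values (CART convention).  Each child predicts
#' its majority class with probability equal to the majority fraction in
#' that child.  If no split lowers the impurity below the root's, the
#' stump degenerates to a single leaf predicting the root majority.
#'
#' Deterministic conventions: a feature equal to the threshold goes to
#' the right child; Gini ties between candidate splits are broken toward
#' the smallest threshold; a 50/50 child predicts class 0 (insoluble)
#' with probability 0.5.
#'
#' @param x Numeric feature vector (length >= 2, finite).
#' @param y Binary labels (0/1), same length.
#' @param scale_id Optional id of the scale the feature came from.
#' @return Object of class `decision_stump` with fields `scale_id`,
#'   `threshold` (`NA` for a leaf-only stump), `left_class`,
#'   `right_class`, `left_prob`, `right_prob`, `is_leaf_only`,
#'   `training_accuracy` and `n`.
#' @examples
#' fit_stump(c(0, 1), c(0, 1))
#' @export
fit_stump <- function(x, y, scale_id = NA_character_) {
  if (length(x) != length(y)) stopf("feature and label lengths differ")
  n <- length(x)
  if (n < 2L) stopf("fit_stump needs at least 2 observations, got %d", n)
  if (!all(is.finite(x))) stopf("non-finite feature values")
  if (!is_binary_labels(y)) stopf("labels must be 0/1")
  y <- as.integer(y)

  majority <- function(n1, n0) {
    # returns c(class, prob); tie -> class 0, prob 0.5
    if (n1 > n0) c(1L, n1 / (n1 + n0)) else c(0L, n0 / (n1 + n0))
  }

  n1 <- sum(y)
  n0 <- n - n1
  root_gini <- 1 - (n1 / n)^2 - (n0 / n)^2
  root <- majority(n1, n0)

  leaf_only <- function() {
    structure(list(scale_id = scale_id, threshold = NA_real_,
                   left_class = as.integer(root[1L]),
                   right_class = as.integer(root[1L]),
                   left_prob = root[2L], right_prob = root[2L],
                   is_leaf_only = TRUE,
                   training_accuracy = max(n1, n0) / n, n = n),
              class = "decision_stump")
  }

  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  cut_at <- which(diff(xs) > 0)          # split after position i
  if (length(cut_at) == 0L) return(leaf_only())

  cum1 <- cumsum(ys)
  nL <- cut_at
  posL <- cum1[cut_at]
  negL <- nL - posL
  nR <- n - nL
  posR <- n1 - posL
  negR <- nR - posR
  giniL <- 1 - (posL / nL)^2 - (negL / nL)^2
  giniR <- 1 - (posR / nR)^2 - (negR / nR)^2
  wgini <- (nL * giniL + nR * giniR) / n

  # smallest threshold wins Gini ties; the tolerance absorbs float noise
  # between algebraically equal candidate impurities
  best <- which(wgini <= min(wgini) + 1e-12)[1L]
  if (wgini[best] >= root_gini - 1e-12) return(leaf_only())

  i <- cut_at[best]
  thr <- (xs[i] + xs[i + 1L]) / 2
  left <- majority(posL[best], negL[best])
  right <- majority(posR[best], negR[best])
  acc <- (max(posL[best], negL[best]) + max(posR[best], negR[best])) / n
  structure(list(scale_id = scale_id, threshold = thr,
                 left_class = as.integer(left[1L]),
                 right_class = as.integer(right[1L]),
                 left_prob = left[2L], right_prob = right[2L],
                 is_leaf_only = FALSE,
                 training_accuracy = acc, n = n),
            class = "decision_stump")
}

#' @export
print.decision_stump <- function(x, ...) {
  if (x$is_leaf_only) {
    cat(sprintf("<decision_stump%s> leaf only: class %d (p = %.3f), train acc %.3f\n",
                if (is.na(x$scale_id)) "" else paste0(" ", x$scale_id),
                x$left_class, x$left_prob, x$training_accuracy))
  } else {
    cat(sprintf(
      "<decision_stump%s> x < %.4g -> %d (p = %.3f); x >= %.4g -> %d (p = %.3f); train acc %.3f\n",
      if (is.na(x$scale_id)) "" else paste0(" ", x$scale_id),
      x$threshold, x$left_class, x$left_prob,
      x$threshold, x$right_class, x$right_prob, x$training_accuracy))
  }
  invisible(x)
}

#' Predict from a decision stump
#'
#' Features strictly below the threshold fall into the left child; equal
#' or greater features fall into the right child.  Leaf-only stumps
#' return the root majority class for every input.
#'
#' @param object A [fit_stump()] result.
#' @param newdata Numeric feature vector.
#' @param ... Unused.
#' @return `data.frame` with columns `class` (0/1) and `prob` (the
#'   training-set majority fraction of the predicting child).
#' @export
predict.decision_stump <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  if (any(!is.finite(x))) stopf("non-finite feature value in prediction")
  if (object$is_leaf_only) {
    data.frame(class = rep(object$left_class, length(x)),
               prob = rep(object$left_prob, length(x)))
  } else {
    left <- x < object$threshold
    data.frame(class = ifelse(left, object$left_class, object$right_class),
               prob = ifelse(left, object$left_prob, object$right_prob))
  }
}

#' @rdname predict.decision_stump
#' @param stump A `decision_stump`.
#' @param feature Single numeric feature value.
#' @return `stump_predict()`: list with elements `class` and `prob`.
#' @export
stump_predict <- function(stump, feature) {
  p <- predict(stump, feature)
  list(class = p$class[1L], prob = p$prob[1L])
}

#' Training-set accuracy of a stump
#'
#' Fraction of correct class predictions on labelled data; on the data
#' the stump was fit on this equals its stored `training_accuracy` and is
#' the stump's feature importance in the ensemble.
#'
#' @param stump A `decision_stump`.
#' @param x Numeric feature vector.
#' @param y Binary labels.
#' @return Accuracy in \[0, 1\].
#' @export
stump_training_accuracy <- function(stump, x, y) {
  if (length(x) == 0L) stopf("empty evaluation data")
  if (!is_binary_labels(y)) stopf("labels must be 0/1")
  mean(predict(stump, x)$class == as.integer(y))
}
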