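## ROC analysis with Youden-index threshold selection.

#' ROC curve, AUC and Youden-optimal threshold
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' scores plus -Inf and +Inf; at threshold t a case is called positive
#' when its (oriented) score exceeds t. The AUC is computed by the
#' trapezoid rule over the resulting operating points and equals the
#' Mann-Whitney concordant-pair fraction. The optimal threshold maximises
#' Youden's J = sensitivity + specificity - 1; ties are broken toward
#' higher specificity. With `orientation = "lower_is_positive"` scores
#' are negated internally (used for the CE angle, where low values
#' indicate disease) and thresholds are reported on the original scale.
#'
#' @param scores numeric vector of continuous scores.
#' @param labels logical vector (or coercible factor with `positive`
#'   given) marking positive cases; both classes must be present.
#' @param orientation `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`.
#' @param positive when `labels` is not logical, the level counted as
#'   positive.
#' @return A [ROCResult-class].
#' @examples
#' r <- rocCurve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
#' auc(r)  # 1
#' @export
rocCurve <- function(scores, labels,
                     orientation = c("higher_is_positive", "lower_is_positive"),
                     positive = NULL) {
  orientation <- match.arg(orientation)
  if (!is.logical(labels)) {
    if (is.null(positive)) inputError("non-logical 'labels' require 'positive'")
    labels <- as.character(labels) == positive
  }
  if (length(scores) != length(labels))
    inputError("'scores' and 'labels' must have equal length")
  if (any(!is.finite(scores))) inputError("scores must be finite")
  if (!any(labels) || all(labels))
    inputError("both classes must be present for a ROC analysis")
  s <- if (orientation == "lower_is_positive") -scores else scores
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  nPos <- sum(labels); nNeg <- sum(!labels)
  sens <- vapply(thr, function(t) sum(s > t & labels) / nPos, numeric(1))
  spec <- vapply(thr, function(t) sum(s <= t & !labels) / nNeg, numeric(1))
  ## trapezoid over (fpr, tpr), sorted by fpr
  fpr <- 1 - spec
  o <- order(fpr, sens)
  aucVal <- sum(diff(fpr[o]) * (sens[o][-1L] + sens[o][-length(o)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(spec[best])]
  optT <- thr[best]
  if (orientation == "lower_is_positive") {
    optT <- -optT
    thr <- -thr
  }
  new("ROCResult", thresholds = thr, sensitivity = sens,
    specificity = spec, auc = aucVal, optimalThreshold = optT,
    orientation = orientation)
}

#' Youden-optimal operating point
#'
#' @param roc a [ROCResult-class].
#' @return List: `threshold`, `sensitivity`, `specificity`, `youdenJ`.
#' @export
youdenPoint <- function(roc) {
  i <- match(roc@optimalThreshold, roc@thresholds)
  list(threshold = roc@optimalThreshold,
    sensitivity = roc@sensitivity[i], specificity = roc@specificity[i],
    youdenJ = roc@sensitivity[i] + roc@specificity[i] - 1)
}
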