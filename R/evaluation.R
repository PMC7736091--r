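## Agreement and diagnostic-performance statistics for reference-reader
## vs CAD label comparisons. All table statistics are simple closed-form
## ratios of integer counts; rounding happens only at report time.

#' Build a confusion table
#'
#' Cross-tabulates reference labels (rows) against predicted labels
#' (columns) in a fixed class order.
#'
#' @param ref,pred equal-length label vectors (factor or character).
#' @param classes ordered class labels; defaults to the union of levels
#'   in order of first appearance in `ref` then `pred`.
#' @return A [ConfusionTable-class].
#' @export
confusionTable <- function(ref, pred, classes = NULL) {
  ref <- as.character(ref); pred <- as.character(pred)
  if (length(ref) != length(pred))
    inputError("'ref' and 'pred' must have equal length")
  if (length(ref) == 0L) inputError("empty label vectors")
  if (is.null(classes)) classes <- unique(c(ref, pred))
  bad <- setdiff(unique(c(ref, pred)), classes)
  if (length(bad))
    inputError(sprintf("labels outside the class set: %s", paste(bad, collapse = ", ")))
  cnt <- table(factor(ref, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(cnt), length(classes), length(classes),
    dimnames = list(reference = classes, predicted = classes))
  new("ConfusionTable", classes = classes, counts = m)
}

#' Construct a confusion table from a count matrix
#'
#' For tables published as counts (rows = reference, columns = predicted).
#'
#' @param counts square numeric matrix of non-negative integers.
#' @param classes class labels; defaults to `rownames(counts)`.
#' @return A [ConfusionTable-class].
#' @export
confusionTableFromCounts <- function(counts, classes = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(reference = classes, predicted = classes)
  new("ConfusionTable", classes = as.character(classes), counts = counts)
}

.as2x2 <- function(t, positive) {
  if (length(t@classes) != 2L) inputError("a 2 x 2 confusion table is required")
  if (!positive %in% t@classes)
    inputError(sprintf("positive class '%s' not among table classes", positive))
  neg <- setdiff(t@classes, positive)
  cnt <- t@counts
  list(tp = cnt[positive, positive], fn = cnt[positive, neg],
    fp = cnt[neg, positive], tn = cnt[neg, neg])
}

#' Diagnostic metrics from a 2 x 2 confusion table
#'
#' Accuracy (correct / total), sensitivity (true-positive rate),
#' specificity (true-negative rate) and false-positive rate, with the
#' given class taken as positive (disease). Values are exact proportions;
#' use [asPercent()] for report rounding.
#'
#' @param t a 2 x 2 [ConfusionTable-class].
#' @param positive the positive (disease) class label.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `fpr`.
#' @section Errors: undefined-metric error naming the metric when a
#'   required row total is zero.
#' @export
diagnosticMetrics <- function(t, positive) {
  x <- .as2x2(t, positive)
  n <- x$tp + x$fn + x$fp + x$tn
  if (n == 0) undefinedMetricError("accuracy is undefined: empty table")
  if (x$tp + x$fn == 0)
    undefinedMetricError("sensitivity is undefined: no positive reference cases")
  if (x$tn + x$fp == 0)
    undefinedMetricError("specificity is undefined: no negative reference cases")
  list(accuracy = (x$tp + x$tn) / n,
    sensitivity = x$tp / (x$tp + x$fn),
    specificity = x$tn / (x$tn + x$fp),
    fpr = x$fp / (x$tn + x$fp))
}

#' Report a proportion as a percentage
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param digits decimals in the percentage (default 1, the usual report
#'   precision).
#' @return Numeric percentage(s).
#' @export
asPercent <- function(p, digits = 1) round(100 * p, digits)

#' Overall accuracy of a k x k confusion table
#'
#' @param t a [ConfusionTable-class].
#' @return `sum(diag) / n`.
#' @export
multiclassAccuracy <- function(t) {
  n <- sum(t@counts)
  if (n == 0) undefinedMetricError("accuracy is undefined: empty table")
  sum(diag(t@counts)) / n
}

#' Per-class recall of a confusion table
#'
#' Fraction of reference cases of `class` that were predicted as `class`.
#'
#' @param t a [ConfusionTable-class].
#' @param class a class label.
#' @return Proportion.
#' @export
classRecall <- function(t, class) {
  if (!class %in% t@classes) inputError(sprintf("unknown class '%s'", class))
  tot <- sum(t@counts[class, ])
  if (tot == 0)
    undefinedMetricError(sprintf("recall is undefined: no reference cases of '%s'", class))
  t@counts[class, class] / tot
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement,
#' `(po - pe) / (1 - pe)`, with expected agreement `pe` from the
#' marginal products.
#'
#' @param t a [ConfusionTable-class].
#' @return Kappa.
#' @export
cohenKappa <- function(t) {
  cnt <- t@counts
  n <- sum(cnt)
  if (n == 0) undefinedMetricError("kappa is undefined: empty table")
  po <- sum(diag(cnt)) / n
  pe <- sum(rowSums(cnt) * colSums(cnt)) / n^2
  if (pe == 1)
    undefinedMetricError("kappa is undefined: expected agreement equals 1")
  (po - pe) / (1 - pe)
}

#' McNemar test on a paired 2 x 2 table
#'
#' Tests marginal homogeneity (reader vs CAD make the same errors at the
#' same rate) from the discordant counts b and c. The default is the
#' exact two-sided binomial test, `p = min(1, 2 * P[X <= min(b, c)])`
#' with `X ~ Binomial(b + c, 1/2)`, at every table size; the
#' continuity-corrected chi-square variant is available by flag. When
#' `b + c = 0` the test is vacuous and `p = 1` is returned with a note.
#'
#' @param t a 2 x 2 [ConfusionTable-class] (or 2 x 2 count matrix).
#' @param method `"exact"` (default) or `"chisq"`.
#' @return List: `statistic` (`NA` for the exact test), `p`, `b`, `c`,
#'   `method`, and `note` when the test is vacuous.
#' @export
mcnemarTest <- function(t, method = c("exact", "chisq")) {
  method <- match.arg(method)
  cnt <- if (is(t, "ConfusionTable")) t@counts else as.matrix(t)
  if (nrow(cnt) != 2L || ncol(cnt) != 2L)
    inputError("mcnemarTest requires a 2 x 2 table")
  b <- cnt[1L, 2L]; c_ <- cnt[2L, 1L]
  if (b + c_ == 0)
    return(list(statistic = NA_real_, p = 1,
      b = b, c = c_, method = method,
      note = "no discordant pairs; test is vacuous"))
  if (method == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, c_), b + c_, 0.5))
    list(statistic = NA_real_, p = p, b = b, c = c_, method = "exact")
  } else {
    stat <- (abs(b - c_) - 1)^2 / (b + c_)
    list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
      b = b, c = c_, method = "chisq")
  }
}

#' Bowker test of symmetry on a k x k table
#'
#' Generalises the McNemar test to k classes:
#' `X2 = sum over i<j of (n_ij - n_ji)^2 / (n_ij + n_ji)`, chi-square
#' with one degree of freedom per contributing pair. Pairs with
#' `n_ij + n_ji = 0` contribute nothing and drop a degree of freedom.
#' A 2 x 2 input delegates to the exact [mcnemarTest()].
#'
#' @param t a k x k [ConfusionTable-class] (or count matrix), k >= 2.
#' @return List: `statistic`, `df`, `p`.
#' @export
bowkerTest <- function(t) {
  cnt <- if (is(t, "ConfusionTable")) t@counts else as.matrix(t)
  k <- nrow(cnt)
  if (k != ncol(cnt) || k < 2L) inputError("bowkerTest requires a square table, k >= 2")
  if (k == 2L) {
    m <- mcnemarTest(cnt)
    return(list(statistic = m$statistic, df = 1L, p = m$p))
  }
  stat <- 0; df <- 0L
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    s <- cnt[i, j] + cnt[j, i]
    if (s > 0) {
      stat <- stat + (cnt[i, j] - cnt[j, i])^2 / s
      df <- df + 1L
    }
  }
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Pearson correlation between paired measurements
#'
#' Product-moment correlation with the two-sided t-test p-value; thin
#' wrapper over [stats::cor.test()].
#'
#' @param x,y paired numeric vectors, `n >= 3`, nonzero variance each.
#' @return List: `r`, `p`, `n`.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) inputError("'x' and 'y' must have equal length")
  if (length(x) < 3L) inputError("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    undefinedMetricError("correlation is undefined: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cronbach's alpha for two repeated measurements
#'
#' Internal-consistency coefficient for a two-item design (test-retest of
#' the same angle): `alpha = 2 * (1 - (var(m1) + var(m2)) / var(m1 + m2))`.
#'
#' @param m1,m2 paired numeric vectors, `n >= 3`.
#' @return Alpha.
#' @export
cronbachAlpha <- function(m1, m2) {
  if (length(m1) != length(m2)) inputError("'m1' and 'm2' must have equal length")
  if (length(m1) < 3L) inputError("need at least 3 pairs")
  vt <- stats::var(m1 + m2)
  if (vt == 0) undefinedMetricError("alpha is undefined: zero total variance")
  2 * (1 - (stats::var(m1) + stats::var(m2)) / vt)
}
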