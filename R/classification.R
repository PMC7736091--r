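## Mapping angles to development labels: clinical threshold rules and an
## SVM trained on the three indices.
##
## Boundary semantics follow the clinical wording exactly, with strict
## inequalities: Toennis dysplasia iff angle > 10 (10.0 itself is
## normal); Sharp dysplasia iff angle > 45; CE dysplasia iff angle < 20,
## borderline for 20 <= angle <= 25 (closed interval), normal above 25.
## Only the CE rule can produce "borderline".

#' Development label levels
#'
#' The ordered label set used throughout: `normal`, `borderline`,
#' `dysplasia`. `dichotomizeCE()` folds borderline and dysplasia into
#' `abnormal`.
#' @export
developmentLevels <- function() c("normal", "borderline", "dysplasia")

.checkAngles <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    inputError(sprintf("%s angles must be finite numbers", what))
  x
}

#' Threshold classification of hip development
#'
#' Vectorised clinical threshold rules. `classifyTonnis()` labels
#' dysplasia for angles strictly greater than 10 degrees;
#' `classifySharp()` for angles strictly greater than 45 degrees;
#' `classifyCE()` labels dysplasia strictly below 20 degrees, borderline
#' in the closed interval [20, 25] and normal above.
#'
#' @param angle numeric vector of angles in degrees (finite).
#' @return Factor with levels [developmentLevels()].
#' @examples
#' classifyTonnis(c(10, 10.1))   # normal, dysplasia
#' classifyCE(c(19.999, 22, 47)) # dysplasia, borderline, normal
#' @export
classifyTonnis <- function(angle) {
  angle <- .checkAngles(angle, "Toennis")
  factor(ifelse(angle > 10, "dysplasia", "normal"), levels = developmentLevels())
}

#' @rdname classifyTonnis
#' @export
classifySharp <- function(angle) {
  angle <- .checkAngles(angle, "Sharp")
  factor(ifelse(angle > 45, "dysplasia", "normal"), levels = developmentLevels())
}

#' @rdname classifyTonnis
#' @export
classifyCE <- function(angle) {
  angle <- .checkAngles(angle, "CE")
  factor(ifelse(angle < 20, "dysplasia",
    ifelse(angle <= 25, "borderline", "normal")),
    levels = developmentLevels())
}

#' Collapse CE labels to normal/abnormal
#'
#' Borderline and dysplasia are grouped as `abnormal`; equivalent to a
#' single dichotomous threshold at CE <= 25.
#'
#' @param label factor or character vector of development labels.
#' @return Factor with levels `normal`, `abnormal`.
#' @export
dichotomizeCE <- function(label) {
  label <- as.character(label)
  bad <- !label %in% developmentLevels()
  if (any(bad))
    inputError(sprintf("unknown development label(s): %s",
      paste(unique(label[bad]), collapse = ", ")))
  factor(ifelse(label == "normal", "normal", "abnormal"),
    levels = c("normal", "abnormal"))
}

#' Apply a threshold rule by name
#'
#' @param angles data.frame of measurements (needs the `*_deg` column for
#'   the rule).
#' @param rule `"tonnis"`, `"sharp"` or `"ce"`.
#' @return Factor of labels, one per row.
#' @export
classifyByRule <- function(angles, rule = c("tonnis", "sharp", "ce")) {
  rule <- match.arg(rule)
  switch(rule,
    tonnis = classifyTonnis(angles$tonnis_deg),
    sharp = classifySharp(angles$sharp_deg),
    ce = classifyCE(angles$ce_deg))
}

#' SVM hyper-parameter specification
#'
#' Defaults mirror the validated configuration: polynomial kernel of
#' degree 2 with penalty coefficient C = 0.3, `coef0 = 0`, and the kernel
#' coefficient gamma = 1 / (n_features * var(X)) computed on the raw
#' training features (the "scale" convention). The angle features are
#' deliberately not centred: with `coef0 = 0` an even-degree polynomial
#' kernel is symmetric under negating the feature vector, so centred
#' two-cluster data would become inseparable; on raw angle values (which
#' live well away from the origin) the homogeneous quadratic kernel
#' separates cleanly.
#'
#' @param degree polynomial degree.
#' @param cost penalty coefficient C.
#' @param coef0 kernel offset.
#' @param gamma kernel coefficient; `NULL` (default) = variance-scaled.
#' @param seed integer seed fixed before fitting, for reproducibility.
#' @return A list of class `svmSpec`.
#' @export
svmSpec <- function(degree = 2L, cost = 0.3, coef0 = 0, gamma = NULL,
                    seed = 1L) {
  structure(list(degree = as.integer(degree), cost = cost, coef0 = coef0,
    gamma = gamma, seed = as.integer(seed)), class = "svmSpec")
}

.featureMatrix <- function(features) {
  m <- as.matrix(as.data.frame(features)[, c("tonnis_deg", "sharp_deg", "ce_deg")])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) inputError("SVM features must be finite")
  m
}

#' Fit the development SVM
#'
#' Trains a polynomial-kernel support vector machine on the three raw
#' angle indices (no internal centring; see [svmSpec()] for why).
#' Fitting is deterministic for identical inputs and seed.
#'
#' @param features data.frame or matrix with columns `tonnis_deg`,
#'   `sharp_deg`, `ce_deg`.
#' @param labels factor (or coercible) of development labels, at least
#'   two classes present.
#' @param spec an [svmSpec()].
#' @return An object of class `hipSvmFit` with elements `model` (the
#'   underlying [e1071::svm] fit), `nFeatures`, `levels`, `spec`,
#'   `gamma`.
#' @export
svmFit <- function(features, labels, spec = svmSpec()) {
  x <- .featureMatrix(features)
  y <- droplevels(factor(labels))
  if (nrow(x) != length(y)) inputError("features and labels differ in length")
  if (nlevels(y) < 2L)
    inputError("SVM training needs at least two classes in 'labels'")
  gamma <- spec$gamma
  if (is.null(gamma)) gamma <- 1 / (ncol(x) * mean((x - mean(x))^2))
  set.seed(spec$seed)
  model <- e1071::svm(x, y, kernel = "polynomial", degree = spec$degree,
    cost = spec$cost, coef0 = spec$coef0, gamma = gamma, scale = FALSE)
  structure(list(model = model, nFeatures = ncol(x),
    levels = levels(y), spec = spec, gamma = gamma), class = "hipSvmFit")
}

#' Predict development labels with a fitted SVM
#'
#' @param fit a `hipSvmFit` from [svmFit()].
#' @param features data.frame or matrix with the three angle columns.
#' @param decisionValues return the decision values as an attribute.
#' @return Factor of predicted labels (levels as trained).
#' @export
svmPredict <- function(fit, features, decisionValues = FALSE) {
  stopifnot(inherits(fit, "hipSvmFit"))
  x <- .featureMatrix(features)
  if (ncol(x) != fit$nFeatures)
    inputError("feature count does not match the fitted model")
  p <- predict(fit$model, x, decision.values = decisionValues)
  out <- factor(as.character(p), levels = fit$levels)
  if (decisionValues)
    attr(out, "decision.values") <- attr(p, "decision.values")
  out
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Folds are stratified by class and assigned from a fixed seed, so the
#' protocol is reproducible. Returns the pooled out-of-fold accuracy.
#'
#' @inheritParams svmFit
#' @param nfolds number of folds.
#' @param seed seed for the fold assignment.
#' @return A list: `accuracy`, `predictions` (out-of-fold, in input
#'   order), `folds` (fold id per row).
#' @export
svmCrossValidate <- function(features, labels, spec = svmSpec(),
                             nfolds = 5L, seed = 1L) {
  x <- .featureMatrix(features)
  y <- droplevels(factor(labels))
  if (nlevels(y) < 2L) inputError("cross-validation needs at least two classes")
  n <- nrow(x)
  folds <- integer(n)
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (f in seq_len(nfolds)) {
    test <- folds == f
    if (!any(test)) next
    fit <- svmFit(x[!test, , drop = FALSE], y[!test], spec)
    pred[test] <- svmPredict(fit, x[test, , drop = FALSE])
  }
  list(accuracy = mean(pred == y, na.rm = TRUE), predictions = pred,
    folds = folds)
}
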