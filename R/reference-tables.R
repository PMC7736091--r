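## Published agreement tables of the clinical validation cohort that
## motivated this package's defaults: 248 adult hips, imaging-physician
## threshold labels as the reference standard, CAD threshold labels as
## the prediction. These count tables are the canonical worked examples
## for the evaluation module.

#' Reference confusion tables from the clinical validation cohort
#'
#' Count tables (rows = reference reader, columns = CAD) for the 248-hip
#' validation cohort:
#' \describe{
#'   \item{`tonnis`}{2 x 2 normal/dysplasia table for the Toennis rule.}
#'   \item{`sharp`}{2 x 2 table for the Sharp rule.}
#'   \item{`ce3`}{3 x 3 normal/dysplasia/borderline table for the CE
#'     rule.}
#'   \item{`ce2`}{2 x 2 table after folding borderline and dysplasia
#'     into `abnormal`.}
#' }
#' Feeding these into [diagnosticMetrics()], [cohenKappa()],
#' [mcnemarTest()] and [bowkerTest()] reproduces the cohort's published
#' performance figures; see the methods vignette.
#'
#' @return A named list of [ConfusionTable-class] objects.
#' @examples
#' tabs <- referenceCohortTables()
#' asPercent(diagnosticMetrics(tabs$tonnis, positive = "dysplasia")$accuracy)
#' @export
referenceCohortTables <- function() {
  list(
    tonnis = confusionTableFromCounts(
      rbind(normal = c(155, 8), dysplasia = c(19, 66)),
      classes = c("normal", "dysplasia")),
    sharp = confusionTableFromCounts(
      rbind(normal = c(204, 9), dysplasia = c(8, 27)),
      classes = c("normal", "dysplasia")),
    ce3 = confusionTableFromCounts(
      rbind(normal = c(154, 2, 18),
            dysplasia = c(0, 23, 4),
            borderline = c(6, 14, 27)),
      classes = c("normal", "dysplasia", "borderline")),
    ce2 = confusionTableFromCounts(
      rbind(normal = c(154, 20), abnormal = c(6, 68)),
      classes = c("normal", "abnormal"))
  )
}

#' Reference cohort summary statistics
#'
#' Per-angle means, SDs and ranges of the validation cohort for both
#' methods (physician and CAD), used as the defaults of
#' [cohortParams()] and as plausible phantom target ranges.
#'
#' @return A data.frame with columns `angle`, `method`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
referenceCohortSummary <- function() {
  data.frame(
    angle = rep(c("tonnis", "sharp", "ce"), each = 2L),
    method = rep(c("physician", "cad"), 3L),
    mean = c(8.490, 7.967, 39.897, 40.885, 28.129, 26.837),
    sd = c(6.510, 7.268, 4.178, 4.576, 8.090, 8.088),
    min = c(-8.000, -7.770, 30.600, 27.840, -4.000, -1.625),
    max = c(33.000, 33.050, 55.600, 56.182, 47.000, 44.350),
    stringsAsFactors = FALSE)
}
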