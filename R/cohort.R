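## Paired physician/CAD measurement cohorts. Latent per-hip angle triples
## are drawn from a correlated trivariate normal; physician and CAD
## observations add independent reader noise. Noise is calibrated
## analytically: with latent SD = sigma * sqrt(0.9) and reader noise
## SD = sigma * sqrt(0.1) per method, the observed per-method SD equals
## sigma and corr(physician, CAD) = 0.9 in expectation — the regime of a
## well-validated semiautomatic system.

#' Cohort simulation parameters
#'
#' Defaults reproduce the reference clinical cohort: n = 248 hips;
#' per-angle means 8.490 / 39.897 / 28.129 degrees and SDs 6.510 /
#' 4.178 / 8.090 degrees for Toennis / Sharp / CE (physician scale);
#' inter-angle latent correlations Toennis-Sharp +0.4, Toennis-CE -0.6,
#' Sharp-CE -0.5 (clinically plausible, configurable); reader noise
#' calibrated for corr(physician, CAD) = 0.9 per angle.
#'
#' @param nHips number of hips (>= 10).
#' @param means,sds named per-angle latent-scale means and total SDs
#'   (order: tonnis, sharp, ce).
#' @param corr 3 x 3 inter-angle correlation matrix of the latent
#'   triples (must be positive semi-definite).
#' @param physicianNoiseSd,cadNoiseSd per-angle reader noise SDs;
#'   `NULL` = calibrated default `sds * sqrt(0.1)`.
#' @param seed integer seed.
#' @return A list of class `cohortParams`.
#' @export
cohortParams <- function(nHips = 248L,
                         means = c(tonnis = 8.490, sharp = 39.897, ce = 28.129),
                         sds = c(tonnis = 6.510, sharp = 4.178, ce = 8.090),
                         corr = rbind(c(1, 0.4, -0.6),
                                      c(0.4, 1, -0.5),
                                      c(-0.6, -0.5, 1)),
                         physicianNoiseSd = NULL, cadNoiseSd = NULL,
                         seed = 1L) {
  if (nHips < 10L) inputError("nHips must be at least 10")
  if (length(means) != 3L || length(sds) != 3L || any(sds <= 0))
    inputError("means and sds must be length-3 (tonnis, sharp, ce), sds positive")
  corr <- as.matrix(corr)
  if (any(dim(corr) != 3L) || any(abs(corr - t(corr)) > 1e-12))
    inputError("corr must be a symmetric 3 x 3 matrix")
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    inputError("corr must be positive semi-definite")
  if (is.null(physicianNoiseSd)) physicianNoiseSd <- sds * sqrt(0.1)
  if (is.null(cadNoiseSd)) cadNoiseSd <- sds * sqrt(0.1)
  if (any(physicianNoiseSd < 0) || any(cadNoiseSd < 0))
    inputError("noise SDs must be non-negative")
  structure(list(nHips = as.integer(nHips), means = means, sds = sds,
    corr = corr, physicianNoiseSd = physicianNoiseSd,
    cadNoiseSd = cadNoiseSd, seed = as.integer(seed)),
    class = "cohortParams")
}

#' Simulate a paired physician/CAD measurement cohort
#'
#' Draws `nHips` latent angle triples from the trivariate normal implied
#' by `params` (latent SD = `sds * sqrt(1 - (noise/sds)^2)` so that the
#' observed per-method SD matches `sds` under the calibrated defaults),
#' adds independent physician and CAD noise, and attaches the threshold
#' labels for each method and index. Physician labels serve as the
#' reference standard downstream.
#'
#' @param params a [cohortParams()].
#' @return A data.frame with one row per hip: `hip_id`, `side`, latent
#'   (`*_true`), physician (`*_phys`) and CAD (`*_cad`) angles, and the
#'   label columns `label_<rule>_phys` / `label_<rule>_cad` (plus the
#'   dichotomised CE labels `label_ce2_*`).
#' @examples
#' coh <- simulateCohort(cohortParams(nHips = 50, seed = 7))
#' with(coh, cor(tonnis_phys, tonnis_cad))
#' @export
simulateCohort <- function(params = cohortParams()) {
  stopifnot(inherits(params, "cohortParams"))
  n <- params$nHips
  latentVar <- params$sds^2 - params$physicianNoiseSd^2
  if (any(latentVar <= 0))
    inputError("noise SDs too large: latent variance would be non-positive")
  latentSd <- sqrt(latentVar)
  Sigma <- diag(latentSd) %*% params$corr %*% diag(latentSd)
  .withSeed(params$seed, {
    lat <- MASS::mvrnorm(n, mu = params$means, Sigma = Sigma)
    phys <- lat + matrix(stats::rnorm(3L * n), n, 3L) %*% diag(params$physicianNoiseSd)
    cad <- lat + matrix(stats::rnorm(3L * n), n, 3L) %*% diag(params$cadNoiseSd)
    out <- data.frame(
      hip_id = sprintf("hip%04d", seq_len(n)),
      side = rep_len(c("right", "left"), n),
      tonnis_true = lat[, 1L], sharp_true = lat[, 2L], ce_true = lat[, 3L],
      tonnis_phys = phys[, 1L], sharp_phys = phys[, 2L], ce_phys = phys[, 3L],
      tonnis_cad = cad[, 1L], sharp_cad = cad[, 2L], ce_cad = cad[, 3L],
      stringsAsFactors = FALSE)
    out$label_tonnis_phys <- as.character(classifyTonnis(out$tonnis_phys))
    out$label_tonnis_cad <- as.character(classifyTonnis(out$tonnis_cad))
    out$label_sharp_phys <- as.character(classifySharp(out$sharp_phys))
    out$label_sharp_cad <- as.character(classifySharp(out$sharp_cad))
    out$label_ce_phys <- as.character(classifyCE(out$ce_phys))
    out$label_ce_cad <- as.character(classifyCE(out$ce_cad))
    out$label_ce2_phys <- as.character(dichotomizeCE(out$label_ce_phys))
    out$label_ce2_cad <- as.character(dichotomizeCE(out$label_ce_cad))
    out
  })
}
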