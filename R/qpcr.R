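## Efficiency-corrected relative expression: dilution-series efficiency,
## Pfaffl-style reference-normalized ratios and a REST-style randomization
## significance test.

#' Amplification efficiency from a cDNA dilution series
#'
#' Least-squares fit of mean Cq on log10(dilution); the amplification factor
#' is \code{E = 10^(-1/slope)} (fold per cycle, 2 for perfect doubling) and
#' the fractional efficiency \code{E - 1}.
#'
#' @param dilution dilution factors, one per level (e.g. 1, 0.1, 0.01,
#'   0.001); at least 3 levels.
#' @param cq numeric matrix or data.frame of Cq values with one row per
#'   dilution level (columns = replicates), or a vector of per-level means.
#' @return list of class \code{"EfficiencyEstimate"} with slope, E,
#'   efficiency, r2.
#' @export
efficiencyFromDilution <- function(dilution, cq) {
  dilution <- as.numeric(dilution)
  if (length(unique(dilution)) < 3L) stop("need at least 3 dilution levels")
  if (is.null(dim(cq))) cq <- matrix(cq, ncol = 1L)
  cq <- as.matrix(cq)
  if (nrow(cq) != length(dilution))
    stop("cq must have one row per dilution level")
  if (any(cq <= 0)) stop("Cq values must be positive")
  meanCq <- rowMeans(cq)
  x <- log10(dilution)
  if (stats::sd(meanCq) == 0 || stats::sd(x) == 0)
    stop("degenerate dilution series: zero variance")
  fit <- stats::lm(meanCq ~ x)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) stop("Cq must decrease with template amount; slope >= 0")
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((meanCq - mean(meanCq))^2)
  structure(list(slope = slope, E = 10^(-1 / slope),
                 efficiency = 10^(-1 / slope) - 1, r2 = r2),
            class = "EfficiencyEstimate")
}

#' Efficiency-corrected expression ratio (Pfaffl method)
#'
#' \code{ratio = E_target^dCq_target / E_ref^dCq_ref}, with
#' \code{dCq = mean control Cq - mean sample Cq} so that upregulation in the
#' sample gives a ratio > 1. Reduces to \code{2^(-ddCq)} when both
#' amplification factors are 2.
#'
#' @param eTarget,eRef amplification factors (fold per cycle, in (1, 2] for
#'   real assays).
#' @param dCqTarget,dCqRef Cq displacements (control minus sample).
#' @return expression ratio (> 0).
#' @export
pfafflRatio <- function(eTarget, dCqTarget, eRef, dCqRef) {
  if (any(c(eTarget, eRef) <= 0)) stop("amplification factor must be positive")
  if (any(c(eTarget, eRef) <= 1))
    stop("amplification factor must exceed 1 (no amplification otherwise)")
  if (any(c(eTarget, eRef) > 2 + 1e-9))
    warning("amplification factor above 2 (super-doubling) is not physical")
  eTarget^dCqTarget / eRef^dCqRef
}

#' REST-style randomization test for expression ratios
#'
#' The observed statistic is the efficiency-corrected ratio of the sample
#' versus control group, normalized by the reference gene. Group labels of
#' whole replicates (their target and reference Cq kept paired) are permuted;
#' the p-value is the fraction of permutations whose absolute log-ratio
#' displacement is at least the observed one (with the add-one correction).
#' Deterministic given \code{seed}.
#'
#' @param sampleCq,controlCq data.frames with numeric columns \code{target}
#'   and \code{reference} (one row per replicate; >= 3 per group).
#' @param eTarget,eRef amplification factors.
#' @param iterations number of random permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with ratio, p, iterations, seed.
#' @export
randomizationTest <- function(sampleCq, controlCq, eTarget, eRef,
                              iterations = 10000L, seed = NULL) {
  need <- c("target", "reference")
  stopifnot(all(need %in% names(sampleCq)), all(need %in% names(controlCq)))
  ns <- nrow(sampleCq); nc <- nrow(controlCq)
  if (ns < 3L || nc < 3L) stop("need at least 3 replicates per group")
  if (!is.null(seed)) set.seed(seed)
  ratioOf <- function(sT, sR, cT, cR)
    pfafflRatio(eTarget, mean(cT) - mean(sT), eRef, mean(cR) - mean(sR))
  obs <- ratioOf(sampleCq$target, sampleCq$reference,
                 controlCq$target, controlCq$reference)
  poolT <- c(sampleCq$target, controlCq$target)
  poolR <- c(sampleCq$reference, controlCq$reference)
  n <- ns + nc
  idx <- replicate(iterations, sample.int(n, ns))
  sT <- matrix(poolT[idx], nrow = ns)
  sR <- matrix(poolR[idx], nrow = ns)
  mST <- colMeans(sT); mSR <- colMeans(sR)
  mCT <- (sum(poolT) - ns * mST) / nc
  mCR <- (sum(poolR) - ns * mSR) / nc
  permLog <- (mCT - mST) * log(eTarget) - (mCR - mSR) * log(eRef)
  p <- (1 + sum(abs(permLog) >= abs(log(obs)) - 1e-12)) / (iterations + 1)
  list(ratio = obs, p = p, iterations = as.integer(iterations), seed = seed)
}

#' Simulate a Cq dilution series with known efficiency
#'
#' Cq values follow \code{Cq = cq0 - log(d)/log(E) + noise}; with E = 2 the
#' spacing is 3.32 cycles per 10-fold dilution.
#'
#' @param E true amplification factor.
#' @param dilution dilution levels (default 1, 0.1, 0.01, 0.001).
#' @param replicates technical replicates per level (default 3).
#' @param cq0 Cq of the undiluted template.
#' @param noiseSd Gaussian Cq noise SD.
#' @return list with \code{dilution} and \code{cq} (levels x replicates
#'   matrix).
#' @export
simulateDilutionSeries <- function(E, dilution = c(1, 0.1, 0.01, 0.001),
                                   replicates = 3L, cq0 = 18, noiseSd = 0.05) {
  mu <- cq0 - log(dilution) / log(E)
  cq <- matrix(stats::rnorm(length(dilution) * replicates,
                            mean = rep(mu, replicates), sd = noiseSd),
               nrow = length(dilution))
  list(dilution = dilution, cq = cq)
}
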