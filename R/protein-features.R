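## Protein-level characterization: Guruprasad instability index, Bjellqvist
## isoelectric point, composition bias, heptad coiled-coil scan and
## domain-loss reporting for truncated products.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

## Guruprasad, Reddy & Pandit (1990) dipeptide instability weight values
## (DIWV); rows = first residue, columns = second residue.
.DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(.AA20, .AA20))

#' Guruprasad instability index
#'
#' \code{II = (10/L) * sum_i DIWV(aa_i, aa_{i+1})} over the published
#' 400-entry dipeptide weight table. Values of 40 and above classify the
#' protein as unstable in vitro. Non-standard residues (X, B, Z, ...) are
#' removed with a warning and L renormalized.
#'
#' @param protein amino-acid string (one-letter code), length >= 2.
#' @return unitless instability index.
#' @export
instabilityIndex <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  keep <- aa %in% .AA20
  if (!all(keep)) {
    warning("non-standard residue(s) skipped: ",
            paste(unique(aa[!keep]), collapse = ","))
    aa <- aa[keep]
  }
  L <- length(aa)
  if (L < 2L) stop("protein must have at least 2 standard residues")
  idx <- cbind(match(aa[-L], .AA20), match(aa[-1L], .AA20))
  (10 / L) * sum(.DIWV[idx])
}

#' Bjellqvist pKa set
#'
#' The classic pKa values used by the ProtParam-style theoretical pI:
#' side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0;
#' C-terminus 3.55 (4.55 when ending in D, 4.75 in E); N-terminus 7.5 with
#' residue-specific overrides (A 7.59, M 7.0, S 6.93, P 8.36, T 6.82,
#' V 7.44, E 7.7).
#'
#' @return a list with components \code{positive}, \code{negative},
#'   \code{ntermByResidue}, \code{ctermByResidue}.
#' @export
bjellqvistPKa <- function() {
  list(
    positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
    negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
    ntermByResidue = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                       V = 7.44, E = 7.7),
    ctermByResidue = c(D = 4.55, E = 4.75)
  )
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over termini and ionizable side chains;
#' strictly decreasing in pH. Degenerate residues are treated as uncharged.
#'
#' @param protein amino-acid string.
#' @param pH pH value(s).
#' @param pKa a pKa set as from \code{\link{bjellqvistPKa}}.
#' @return net charge (vectorized over \code{pH}).
#' @export
netCharge <- function(protein, pH, pKa = bjellqvistPKa()) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (!length(aa)) stop("empty protein")
  counts <- table(aa)
  cnt <- function(r) if (r %in% names(counts)) as.numeric(counts[[r]]) else 0
  ntermK <- pKa$positive[["Nterm"]]
  if (aa[1L] %in% names(pKa$ntermByResidue))
    ntermK <- pKa$ntermByResidue[[aa[1L]]]
  ctermK <- pKa$negative[["Cterm"]]
  if (aa[length(aa)] %in% names(pKa$ctermByResidue))
    ctermK <- pKa$ctermByResidue[[aa[length(aa)]]]
  pos <- function(pk, n) n / (1 + 10^(pH - pk))
  neg <- function(pk, n) -n / (1 + 10^(pk - pH))
  q <- pos(ntermK, 1) + neg(ctermK, 1)
  for (r in c("K", "R", "H")) q <- q + pos(pKa$positive[[r]], cnt(r))
  for (r in c("D", "E", "C", "Y")) q <- q + neg(pKa$negative[[r]], cnt(r))
  q
}

#' Theoretical isoelectric point
#'
#' pH at which the Bjellqvist net charge is zero, by monotone root search.
#'
#' @inheritParams netCharge
#' @param tol pH tolerance of the root (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(protein, pKa = bjellqvistPKa(), tol = 1e-4) {
  f <- function(p) netCharge(protein, p, pKa)
  stats::uniroot(f, c(0, 14), tol = tol)$root
}

#' Residue composition and acidic bias
#'
#' @param protein amino-acid string.
#' @return list with \code{counts} (named integer vector over residues seen)
#'   and \code{acidicFraction} (D+E share of the length).
#' @export
compositionBias <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (!length(aa)) stop("empty protein")
  counts <- table(aa)
  acidic <- sum(aa %in% c("D", "E")) / length(aa)
  list(counts = counts, acidicFraction = acidic)
}

## Heptad-position propensities (positions a-g) from the COILS MTIDK
## residue table; zeros floored at scan time to keep log-space scoring
## defined. Rows: residue; columns: heptad positions a..g.
.MTIDK <- matrix(c(
  # a      b      c      d      e      f      g
  1.297, 1.551, 1.084, 2.612, 0.377, 1.248, 0.877,  # A
  0.824, 0.022, 0.308, 0.152, 0.180, 0.156, 0.044,  # C
  0.030, 2.352, 2.268, 0.237, 0.663, 1.620, 1.448,  # D
  0.262, 3.496, 3.108, 0.998, 5.685, 2.494, 3.048,  # E
  0.531, 0.076, 0.403, 0.662, 0.189, 0.106, 0.013,  # F
  0.045, 0.275, 0.578, 0.216, 0.211, 0.426, 0.156,  # G
  0.347, 0.275, 0.679, 0.395, 0.294, 0.579, 0.213,  # H
  2.597, 0.098, 0.345, 0.894, 0.514, 0.471, 0.431,  # I
  1.375, 2.639, 1.763, 0.191, 1.815, 1.961, 2.795,  # K
  3.167, 0.297, 0.398, 3.902, 0.585, 0.501, 0.483,  # L
  2.240, 0.370, 0.480, 1.409, 0.541, 0.772, 0.663,  # M
  0.835, 1.475, 1.534, 0.039, 1.722, 2.456, 2.280,  # N
  0.000, 0.008, 0.000, 0.013, 0.000, 0.000, 0.000,  # P
  0.179, 2.114, 1.778, 0.631, 2.550, 1.578, 2.526,  # Q
  0.659, 1.163, 1.210, 0.031, 1.358, 1.937, 1.798,  # R
  0.382, 0.583, 1.052, 0.419, 0.525, 0.916, 0.628,  # S
  0.169, 0.702, 0.955, 0.654, 0.791, 0.843, 0.647,  # T
  1.665, 0.403, 0.386, 0.949, 0.211, 0.342, 0.360,  # V
  0.240, 0.000, 0.000, 0.456, 0.019, 0.000, 0.000,  # W
  1.417, 0.090, 0.122, 1.659, 0.190, 0.130, 0.155   # Y
), nrow = 20, byrow = TRUE,
  dimnames = list(.AA20, c("a","b","c","d","e","f","g")))

## Two-Gaussian calibration (globular mean/sd, coiled-coil mean/sd) per
## window length; the probability is the likelihood ratio with a 1:30
## coiled-coil prior, as in the published window-scan method. Constants are
## this package's calibration (see the methods vignette).
.CCGAUSS <- list(
  `14` = c(gm = 0.94, gsd = 0.30, ccm = 1.70, ccsd = 0.32),
  `21` = c(gm = 0.97, gsd = 0.26, ccm = 1.80, ccsd = 0.30),
  `28` = c(gm = 1.00, gsd = 0.24, ccm = 1.85, ccsd = 0.28)
)

#' Sliding-window coiled-coil scan
#'
#' Lupas-style scoring: for every window the geometric-mean heptad propensity
#' is computed in all 7 registers and the best register kept; each residue
#' takes the maximum score over windows covering it; scores are converted to
#' probabilities with a two-Gaussian (coiled-coil vs globular) likelihood
#' ratio at a 1:30 prior; called regions are maximal runs with probability
#' at or above the threshold. Degenerate residues get zero propensity.
#'
#' @param protein amino-acid string, length >= \code{window}.
#' @param window scan window: 14, 21 or 28 (published parameterizations
#'   only; default 28).
#' @param threshold per-residue probability needed inside a region
#'   (default 0.5).
#' @return list with \code{regions} (data.frame: start, end, peak, window)
#'   and \code{probability} (per-residue vector in [0,1]).
#' @export
coiledCoilScan <- function(protein, window = 28L, threshold = 0.5) {
  window <- as.integer(window)
  if (!window %in% c(14L, 21L, 28L))
    stop("window must be one of 14, 21, 28")
  aa <- strsplit(toupper(protein), "")[[1]]
  L <- length(aa)
  if (L < window) stop("protein shorter than the scan window")
  ri <- match(aa, .AA20)
  floorP <- 1e-6
  logP <- log(pmax(.MTIDK, floorP))
  ## logProp[i, pos]: log propensity of residue i at heptad position pos
  logProp <- matrix(log(floorP), nrow = L, ncol = 7L)
  ok <- !is.na(ri)
  if (any(ok)) logProp[ok, ] <- logP[ri[ok], , drop = FALSE]
  nWin <- L - window + 1L
  score <- rep(0, L)
  for (s in seq_len(nWin)) {
    idx <- s:(s + window - 1L)
    best <- -Inf
    for (r in 0:6) {
      hp <- ((seq_len(window) - 1L + r) %% 7L) + 1L
      v <- mean(logProp[cbind(idx, hp)])
      if (v > best) best <- v
    }
    w <- exp(best)
    upd <- idx[score[idx] < w]
    score[upd] <- w
  }
  g <- .CCGAUSS[[as.character(window)]]
  dcc <- stats::dnorm(score, g[["ccm"]], g[["ccsd"]])
  dg <- stats::dnorm(score, g[["gm"]], g[["gsd"]])
  prob <- dcc / (dcc + 30 * dg)
  prob[!is.finite(prob)] <- 0
  call <- prob >= threshold
  r <- rle(call)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  regions <- data.frame(
    start = starts[keep], end = ends[keep],
    peak = vapply(keep, function(k) max(prob[starts[k]:ends[k]]), numeric(1)),
    window = rep(window, length(keep)))
  list(regions = regions, probability = prob)
}

#' Domain status after truncation
#'
#' A domain is intact iff it ends at or before the mutant length, lost iff it
#' starts beyond it, and partial otherwise.
#'
#' @param domains data.frame with columns name, start, end (1-based aa,
#'   inclusive).
#' @param fullLength reference protein length.
#' @param mutantLength length of the truncated product.
#' @return the \code{domains} data.frame with a \code{status} column.
#' @export
truncationReport <- function(domains, fullLength, mutantLength) {
  stopifnot(all(c("name", "start", "end") %in% names(domains)))
  if (any(domains$start < 1L) || any(domains$end > fullLength) ||
      any(domains$start > domains$end))
    stop("domain out of bounds for a protein of length ", fullLength)
  domains$status <- ifelse(domains$end <= mutantLength, "intact",
                    ifelse(domains$start > mutantLength, "lost", "partial"))
  domains
}

#' Full protein feature report
#'
#' @param protein amino-acid string.
#' @param domains optional domain annotation (name/start/end data.frame).
#' @param ccWindow,ccThreshold coiled-coil scan parameters.
#' @return a \code{\linkS4class{ProteinFeatureReport}}.
#' @export
proteinFeatureReport <- function(protein, domains = NULL, ccWindow = 28L,
                                 ccThreshold = 0.5) {
  L <- nchar(protein)
  ii <- instabilityIndex(protein)
  cc <- if (L >= ccWindow) coiledCoilScan(protein, ccWindow, ccThreshold)$regions
        else data.frame(start = integer(), end = integer(),
                        peak = numeric(), window = integer())
  methods::new("ProteinFeatureReport",
    length = as.integer(L), instabilityIndex = ii,
    stabilityClass = if (ii < 40) "stable" else "unstable",
    pI = isoelectricPoint(protein),
    acidicFraction = compositionBias(protein)$acidicFraction,
    coiledCoils = cc,
    domains = if (is.null(domains))
      data.frame(name = character(), start = integer(), end = integer())
      else domains)
}
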