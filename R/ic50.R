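## Fluorescence-polarization competition assays: relative binding, IC50
## fitting (full titration and two-point), prediction-affinity correlation.

#' Relative binding values from a competition curve
#'
#' `y = (FP_sample - FP_free) / (FP_nocomp - FP_free)` per replicate
#' reading; replicates are retained, not pre-averaged. The transform is
#' affine-invariant: adding a constant to all polarization readings
#' (including the references) leaves `y` unchanged.
#'
#' @param conc Competitor concentrations (nM), parallel to `fp`.
#' @param fp Polarization readings (mP).
#' @param fpFree Free-probe polarization (no MHC).
#' @param fpNoComp Polarization with MHC but no competitor.
#' @return data.frame `conc, y`.
#' @export
relativeBinding <- function(conc, fp, fpFree, fpNoComp) {
  if (fpNoComp <= fpFree) stop("invalid assay window")
  if (any(conc <= 0)) stop("concentrations must be positive")
  data.frame(conc = conc, y = (fp - fpFree) / (fpNoComp - fpFree))
}

#' Fit a competition curve to an IC50
#'
#' Nonlinear least squares of `y = 1 / (1 + conc / IC50)` with the IC50
#' parameterized on the log10 scale (the tested concentrations span several
#' orders of magnitude). The confidence interval comes from the fit's
#' parameter covariance. Fits whose IC50 falls outside
#' `[min(conc)/100, 100*max(conc)]`, or that fail to converge, are flagged
#' censored and reported against the tested range (e.g. "> 20000 nM").
#'
#' @param conc Competitor concentrations (nM), >= 2 distinct values.
#' @param y Relative binding values (replicates included).
#' @param level Confidence level for the interval.
#' @return List of class `ic50Fit`: `ic50`, `ci`, `residualSS`, `nPoints`,
#'   `method = "curve"`, `censored`, `label`.
#' @export
fitIC50 <- function(conc, y, level = 0.95) {
  if (length(unique(conc)) < 2L) stop("need >= 2 distinct concentrations")
  df <- data.frame(conc = conc, y = y)
  usable <- df$y > 0 & df$y < 1
  start <- if (any(usable)) {
    stats::median(log10(df$conc[usable] * df$y[usable] /
                          (1 - df$y[usable])))
  } else log10(stats::median(df$conc))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (1 + conc / 10^lp), data = df,
                      start = list(lp = start),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  lo <- min(conc) / 100
  hi <- 100 * max(conc)
  if (is.null(fit)) {
    return(structure(list(ic50 = NA_real_, ci = c(NA_real_, NA_real_),
                          residualSS = NA_real_, nPoints = length(y),
                          method = "curve", censored = TRUE,
                          label = sprintf("> %g", max(conc))),
                     class = "ic50Fit"))
  }
  lp <- stats::coef(fit)[["lp"]]
  se <- sqrt(stats::vcov(fit)[1L, 1L])
  q <- stats::qt(1 - (1 - level) / 2, stats::df.residual(fit))
  ic50 <- 10^lp
  censored <- ic50 < lo || ic50 > hi
  structure(list(
    ic50 = ic50, ci = 10^(lp + c(-1, 1) * q * se),
    residualSS = sum(stats::residuals(fit)^2), nPoints = length(y),
    method = "curve", censored = censored,
    label = if (censored && ic50 > hi) sprintf("> %g", max(conc))
            else if (censored) sprintf("< %g", min(conc))
            else sprintf("%.4g nM", ic50)),
    class = "ic50Fit")
}

#' @export
print.ic50Fit <- function(x, ...) {
  cat("IC50 fit (", x$method, "): ", x$label,
      if (!x$censored)
        sprintf("  [CI %.4g - %.4g]", x$ci[1L], x$ci[2L]),
      "  (n = ", x$nPoints, ")\n", sep = "")
  invisible(x)
}

#' Two-point IC50 estimate
#'
#' For assays limited to two competitor concentrations: each point is
#' inverted through the competition model, `IC50_i = c_i * y_i / (1 - y_i)`
#' (replicates averaged per concentration first), and the estimate is the
#' geometric mean of the two. On noise-free two-point data this equals the
#' full curve fit exactly.
#'
#' @param conc Two distinct concentrations (nM), parallel to `y`.
#' @param y Relative binding values.
#' @return List of class `ic50Fit` with `method = "two_point"`.
#' @export
twoPointIC50 <- function(conc, y) {
  m <- tapply(y, conc, mean)
  if (length(m) != 2L) stop("two-point estimate requires 2 concentrations")
  if (any(m <= 0) || any(m >= 1)) stop("out-of-range binding value")
  cc <- as.numeric(names(m))
  per <- cc * m / (1 - m)
  structure(list(ic50 = exp(mean(log(per))), ci = range(per),
                 residualSS = NA_real_, nPoints = length(y),
                 method = "two_point", censored = FALSE,
                 label = sprintf("%.4g nM", exp(mean(log(per))))),
            class = "ic50Fit")
}

#' Correlate predictions with measured affinity
#'
#' Ordinary least squares of predicted value against (by default) log10
#' measured IC50 over the shared peptides; censored measurements are
#' excluded and counted. The coefficient of determination is returned with
#' the correlation's sign (negative correlations are flagged).
#'
#' @param pred Named numeric vector: peptide -> predicted value.
#' @param measured Named numeric vector: peptide -> measured IC50 (nM);
#'   `NA` marks censored measurements.
#' @param transform `"log10_ic50"` (default) or `"linear"`.
#' @return List `slope, intercept, rSquared, negative, nUsed, nCensored`.
#' @export
correlatePredictions <- function(pred, measured,
                                 transform = c("log10_ic50", "linear")) {
  transform <- match.arg(transform)
  shared <- intersect(names(pred), names(measured))
  cens <- shared[is.na(measured[shared])]
  shared <- setdiff(shared, cens)
  if (length(shared) < 3L) stop("insufficient data")
  x <- if (transform == "log10_ic50") log10(measured[shared])
       else measured[shared]
  fit <- stats::lm(pred[shared] ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
  if (is.nan(r2)) r2 <- 0  # constant predictions explain nothing
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       rSquared = r2, negative = unname(stats::coef(fit)[2L]) < 0,
       nUsed = length(shared), nCensored = length(cens))
}

#' Read plate-format competition data
#'
#' TSV with columns `peptide, conc_nM, replicate, fp_mP`; reference rows
#' use peptide labels `FREE` (free probe) and `NOCOMP` (MHC, no
#' competitor).
#'
#' @param path TSV path.
#' @return List per peptide with `conc`, `fp`, plus `fpFree`, `fpNoComp`.
#' @export
readPlateTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  fpFree <- mean(df$fp_mP[df$peptide == "FREE"])
  fpNoComp <- mean(df$fp_mP[df$peptide == "NOCOMP"])
  peps <- setdiff(unique(df$peptide), c("FREE", "NOCOMP"))
  curves <- lapply(peps, function(p) {
    sub <- df[df$peptide == p, ]
    list(peptide = p, conc = sub$conc_nM, fp = sub$fp_mP)
  })
  names(curves) <- peps
  list(curves = curves, fpFree = fpFree, fpNoComp = fpNoComp)
}
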