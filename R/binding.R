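# Hill-equation representation and fitting of anisotropy titrations.
# The model is the specific-binding form dA = Bmax * x^n / (Kd^n + x^n);
# fitting is bounded Levenberg-Marquardt over all replicate points.

#' Construct a titration curve
#'
#' @param x titrant concentrations, one per observation (replicates share
#'   an x value).
#' @param response anisotropy change relative to the zero-titrant
#'   reference, same length as \code{x}. Raw anisotropy may be supplied
#'   together with \code{baseline}, in which case \code{response -
#'   baseline} is stored.
#' @param replicate optional replicate index per observation.
#' @param condition free-text label.
#' @param xUnit unit of \code{x} (default \code{"uM"}).
#' @param baseline optional reference anisotropy to subtract.
#' @return a \code{\linkS4class{BindingCurve}}
#' @export
bindingCurve <- function(x, response, replicate = NULL,
                         condition = "unnamed", xUnit = "uM",
                         baseline = NULL) {
  if (length(x) != length(response))
    stop("x and response lengths differ")
  if (!is.null(baseline)) response <- response - baseline
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(x), x, FUN = seq_along)
  }
  new("BindingCurve",
      data = data.frame(x = x, replicate = replicate, response = response),
      condition = condition, xUnit = xUnit)
}

#' Hill binding model
#'
#' \eqn{\Delta A(x) = B_{max}\, x^n / (K_d^n + x^n)}: zero at zero titrant,
#' half of \code{bmax} at \code{x = kd}, saturating at \code{bmax}.
#'
#' @param x concentration(s), same units as \code{kd}
#' @param kd half-saturation constant (> 0)
#' @param hillN Hill coefficient (> 0)
#' @param bmax amplitude (> 0)
#' @return predicted anisotropy change(s)
#' @examples
#' hillModel(1, kd = 1, hillN = 1, bmax = 0.2)  # half saturation
#' @export
hillModel <- function(x, kd, hillN, bmax) {
  stopifnot(kd > 0, hillN > 0, bmax > 0)
  bmax * x^hillN / (kd^hillN + x^hillN)
}

# Pooled replicate SD: sqrt of the replicate-variance pooled over all x
# with >= 2 replicates; NA when no x has replication.
.pooledReplicateSD <- function(d) {
  byx <- split(d$response, d$x)
  byx <- byx[lengths(byx) >= 2L]
  if (!length(byx)) return(NA_real_)
  dfree <- sum(lengths(byx) - 1L)
  sqrt(sum(vapply(byx, function(v) (length(v) - 1L) * stats::var(v), 0)) /
       dfree)
}

# Log-interpolated x at half the maximal mean response; falls back to the
# geometric mean of the positive x range when the means never cross it.
.halfSaturationGuess <- function(xs, means, half) {
  pos <- xs > 0
  xs <- xs[pos]; means <- means[pos]
  above <- which(means >= half)
  if (length(above) == 0L || above[1L] == 1L)
    return(exp(mean(log(range(xs)))))
  i <- above[1L]
  x0 <- xs[i - 1L]; x1 <- xs[i]
  y0 <- means[i - 1L]; y1 <- means[i]
  if (y1 == y0) return(x1)
  exp(log(x0) + (half - y0) / (y1 - y0) * (log(x1) - log(x0)))
}

.refusedFit <- function(condition, n) {
  new("HillFit", kd = NA_real_, hillN = NA_real_, bmax = NA_real_,
      se = c(kd = NA_real_, hillN = NA_real_, bmax = NA_real_),
      converged = FALSE, refused = TRUE, rss = NA_real_,
      nObs = n, condition = condition)
}

#' Fit the Hill model to a titration
#'
#' Nonlinear least squares over all replicate points (equal weights) with
#' parameter bounds \code{kd} in \code{[x_min/100, 100 x_max]}, \code{n}
#' in \code{[0.3, 6]} and \code{bmax} in \code{(0, 3 max dA]}.
#' Initialisation: \code{bmax} at the maximal per-concentration mean,
#' \code{kd} at the log-interpolated half-saturation point, \code{n = 1}.
#'
#' When the maximal mean response does not exceed three pooled replicate
#' standard deviations the fit is refused (\code{isRefused} is TRUE): the
#' curve carries no signal distinguishable from well-to-well noise, the
#' operational definition of "no detectable binding". A fit whose optimum
#' lands on a kd bound is returned but flagged not converged.
#'
#' @param curve a \code{\linkS4class{BindingCurve}}
#' @return a \code{\linkS4class{HillFit}}
#' @export
fitHill <- function(curve) {
  d <- curve@data
  xs <- sort(unique(d$x))
  means <- vapply(split(d$response, d$x)[as.character(xs)], mean, 0)
  maxMean <- max(means)
  psd <- .pooledReplicateSD(d)
  if (!is.na(psd) && maxMean <= 3 * psd)
    return(.refusedFit(curve@condition, nrow(d)))
  if (maxMean <= 0)
    return(.refusedFit(curve@condition, nrow(d)))
  xpos <- xs[xs > 0]
  lowerKd <- min(xpos) / 100
  upperKd <- max(xpos) * 100
  start <- list(bmax = maxMean,
                kd = min(max(.halfSaturationGuess(xs, means, maxMean / 2),
                             lowerKd), upperKd),
                n = 1)
  lower <- c(bmax = 1e-12, kd = lowerKd, n = 0.3)
  upper <- c(bmax = 3 * max(d$response), kd = upperKd, n = 6)
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ bmax * x^n / (kd^n + x^n),
                      data = d, start = start,
                      lower = lower[names(start)],
                      upper = upper[names(start)],
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- .refusedFit(curve@condition, nrow(d))
    out@refused <- FALSE
    return(out)
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   setNames(rep(NA_real_, 3L), names(est)))
  atBound <- est[["kd"]] <= lowerKd * (1 + 1e-6) ||
             est[["kd"]] >= upperKd * (1 - 1e-6)
  new("HillFit", kd = est[["kd"]], hillN = est[["n"]],
      bmax = est[["bmax"]],
      se = c(kd = unname(se[["kd"]]), hillN = unname(se[["n"]]),
             bmax = unname(se[["bmax"]])),
      converged = !atBound, refused = FALSE,
      rss = sum(stats::residuals(fit)^2), nObs = nrow(d),
      condition = curve@condition)
}

#' Classify a variant's binding relative to a reference fit
#'
#' Applies the three-way rule used to colour mutant panels: a refused or
#' non-converged fit is \code{negligible}; a fitted Kd more than 2-fold
#' above the reference is \code{reduced}; anything else is
#' \code{comparable_or_better}.
#'
#' @param fit the variant's \code{\linkS4class{HillFit}}
#' @param reference the wild-type \code{HillFit}; must have converged.
#' @return list with \code{category} and \code{reference_kd}
#' @export
classifyVariant <- function(fit, reference) {
  if (!isConverged(reference))
    stop("reference fit did not converge")
  refKd <- kd(reference)
  category <- if (isRefused(fit) || !isConverged(fit)) "negligible"
    else if (kd(fit) > 2 * refKd) "reduced"
    else "comparable_or_better"
  list(category = category, reference_kd = refKd)
}

#' Fit ion-response curves
#'
#' Runs the same Hill machinery with ion concentration as the titration
#' axis (protein held fixed) for a set of ionic species, and flags each
#' species responsive when its fit is accepted and converged.
#'
#' @param curves named list of \code{\linkS4class{BindingCurve}} objects,
#'   one per ion species.
#' @return list with \code{table} (data.frame: ion, kd, hill_n, bmax,
#'   converged, refused, responsive) and \code{fits} (named list of
#'   \code{HillFit})
#' @export
ionResponse <- function(curves) {
  if (!length(curves)) stop("no ion curves supplied")
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    stop("curves must be a named list keyed by ion species")
  fits <- lapply(curves, fitHill)
  tab <- data.frame(
    ion = names(curves),
    kd = vapply(fits, kd, 0),
    hill_n = vapply(fits, hillN, 0),
    bmax = vapply(fits, bmax, 0),
    converged = vapply(fits, isConverged, TRUE),
    refused = vapply(fits, isRefused, TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$responsive <- tab$converged & !tab$refused
  list(table = tab, fits = fits)
}
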