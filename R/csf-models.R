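#' The candidate CSF functional forms
#'
#' Nine parametric forms for the contrast sensitivity function (CSF),
#' each mapping spatial frequency f (cycles per degree) to sensitivity
#' (inverse Michelson contrast threshold) with three or four parameters
#' `alpha`, `beta`, `gamma`, `delta`. All are proportional to the gain
#' `delta`; negative algebraic values are clipped to zero.
#'
#' \describe{
#'   \item{LP (3)}{log parabola: `delta * exp(-(log2(f/alpha)/beta)^2)`.}
#'   \item{dEXP (3)}{double exponential: `delta * f^alpha * exp(-f/beta)`.}
#'   \item{aLP (4)}{asymmetric log parabola: separate left (`beta`) and
#'     right (`gamma`) octave widths around the peak at `alpha`.}
#'   \item{DoG (4)}{difference of Gaussians.}
#'   \item{YQM (4)}{low-pass exponential attenuated by a low-frequency
#'     surround term: `delta * exp(-f/alpha) / (1 + gamma/(1 + (f/beta)^2))`.}
#'   \item{MS (4)}{generalised Gaussian times a linear function of SF:
#'     `delta * (1 - beta + f/alpha) * exp(-(f/alpha)^gamma)`.}
#'   \item{HmH (4)}{difference of hyperbolic secants.}
#'   \item{HmG (4)}{hyperbolic secant minus a Gaussian.}
#'   \item{EmG (4)}{exponential minus a Gaussian.}
#' }
#'
#' The YQM, aLP and MS rows follow the canonical published forms from the
#' CSF-model literature; see the methods vignette for why these three are
#' labelled canonical stand-ins.
#'
#' @return `csf_models()` returns the nine model labels.
#' @name csf_models
NULL

#' @rdname csf_models
#' @export
csf_models <- function() {
  c("YQM", "dEXP", "aLP", "DoG", "LP", "MS", "HmH", "HmG", "EmG")
}

#' Number of free parameters of a CSF form
#' @param model A model label from [csf_models()].
#' @return 3 for `LP` and `dEXP`, otherwise 4.
#' @export
n_csf_params <- function(model) {
  model <- match.arg(model, csf_models())
  if (model %in% c("LP", "dEXP")) 3L else 4L
}

#' CSF parameter set
#'
#' @param model Model label, see [csf_models()].
#' @param alpha,beta Scale/shape parameters (cpd-scale for most forms;
#'   `alpha` is a dimensionless exponent for `dEXP`).
#' @param gamma Dimensionless parameter; ignored (and stored as `NA`) for
#'   the 3-parameter forms `LP` and `dEXP`.
#' @param delta Peak/gain sensitivity (> 0), in units of inverse contrast.
#' @return An object of class `"csf_params"`.
#' @examples
#' p <- csf_params("LP", alpha = 2, beta = 1, delta = 100)
#' csf_sensitivity(p, 2)
#' @export
csf_params <- function(model, alpha, beta, gamma = NA_real_, delta) {
  model <- match.arg(model, csf_models())
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(delta)) {
    stopf("alpha, beta, delta must be finite")
  }
  if (delta <= 0) stopf("delta must be > 0")
  # MS uses beta as a dimensionless linear coefficient that may be zero
  if (model == "MS") {
    if (beta < 0) stopf("MS beta must be >= 0")
  } else if (beta <= 0) {
    stopf("beta must be > 0")
  }
  if (model == "dEXP") {
    if (alpha < 0) stopf("dEXP exponent alpha must be >= 0")
  } else if (alpha <= 0) {
    stopf("alpha must be > 0")
  }
  if (n_csf_params(model) == 4L) {
    if (!is.finite(gamma)) stopf("model '%s' needs a finite gamma", model)
    if (gamma < 0) stopf("gamma must be >= 0")
  } else {
    gamma <- NA_real_
  }
  structure(list(model = model, alpha = alpha, beta = beta,
                 gamma = gamma, delta = delta),
            class = "csf_params")
}

#' @export
print.csf_params <- function(x, ...) {
  cat(sprintf("CSF [%s]: alpha=%.4g beta=%.4g gamma=%s delta=%.4g\n",
              x$model, x$alpha, x$beta,
              if (is.na(x$gamma)) "-" else sprintf("%.4g", x$gamma), x$delta))
  invisible(x)
}

sech <- function(x) 1 / cosh(x)

#' Evaluate a CSF
#'
#' @param params A [csf_params()] object.
#' @param f Spatial frequency in cpd (> 0, vectorised).
#' @return Sensitivity (inverse contrast threshold), clipped at zero.
#' @export
csf_sensitivity <- function(params, f) {
  stopifnot(inherits(params, "csf_params"))
  if (any(!is.finite(f)) || any(f <= 0)) stopf("f must be finite and > 0")
  a <- params$alpha; b <- params$beta; g <- params$gamma; d <- params$delta
  v <- switch(params$model,
    LP   = d * exp(-(log2(f / a) / b)^2),
    dEXP = d * f^a * exp(-f / b),
    aLP  = {
      w <- ifelse(f < a, b, g)
      d * exp(-(log2(f / a) / w)^2)
    },
    DoG  = d * (exp(-(f / a)^2) - g * exp(-(f / b)^2)),
    YQM  = d * exp(-f / a) / (1 + g / (1 + (f / b)^2)),
    MS   = d * (1 - b + f / a) * exp(-(f / a)^g),
    HmH  = d * (sech(f / a) - g * sech(f / b)),
    HmG  = d * (sech(f / a) - g * exp(-(f / b)^2)),
    EmG  = d * (exp(-f / a) - g * exp(-(f / b)^2))
  )
  pmax(v, 0)
}

# Optimisation bounds per model, on the natural parameter scale.
# alpha/beta/delta are searched in log space; gamma linearly.
csf_bounds <- function(model) {
  model <- match.arg(model, csf_models())
  ab <- c(0.05, 60)          # cpd-scale parameters
  switch(model,
    LP   = list(alpha = ab, beta = c(0.1, 10), delta = c(1, 2000)),
    dEXP = list(alpha = c(1e-3, 5), beta = ab, delta = c(1, 2000)),
    aLP  = list(alpha = ab, beta = c(0.1, 10), gamma = c(0.1, 10), delta = c(1, 2000)),
    DoG  = list(alpha = ab, beta = ab, gamma = c(0, 1), delta = c(1, 2000)),
    YQM  = list(alpha = ab, beta = ab, gamma = c(0, 50), delta = c(1, 2000)),
    MS   = list(alpha = ab, beta = c(0, 1), gamma = c(0.5, 10), delta = c(1, 2000)),
    HmH  = list(alpha = ab, beta = ab, gamma = c(0, 1), delta = c(1, 2000)),
    HmG  = list(alpha = ab, beta = ab, gamma = c(0, 1), delta = c(1, 2000)),
    EmG  = list(alpha = ab, beta = ab, gamma = c(0, 1), delta = c(1, 2000))
  )
}
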