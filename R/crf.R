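#' Logistic contrast-response function specification
#'
#' The contrast-response function (CRF) maps log10 Michelson contrast to
#' the probability of a correct orientation judgement. It is a logistic
#' with fixed slope `kappa`, guessing rate `pl` (lower asymptote), upper
#' asymptote `pu` (1 minus the lapse rate), and a targeted performance
#' level `pt` at the threshold contrast `ct`:
#' \deqn{p(c) = s \left(1 + e^{-\kappa (c - t)}\right)^{-1} + p_l}
#' where \eqn{s = 1 - (1 - p_u) - p_l} is the dynamic range and \eqn{t}
#' is a shifted threshold (see [threshold_transform()]) that guarantees
#' \eqn{p(c_t) = p_t} exactly.
#'
#' @param kappa Slope per log10-contrast unit (default 11.8).
#' @param pl Lower asymptote (default 0.5, two-choice guessing).
#' @param pu Upper asymptote (default 0.99).
#' @param pt Targeted performance at threshold (default 0.75).
#' @param ct Optional log10 contrast threshold; location/SF dependent, so
#'   usually supplied per evaluation rather than stored here.
#' @return An object of class `"crf_spec"`.
#' @export
crf_spec <- function(kappa = 11.8, pl = 0.5, pu = 0.99, pt = 0.75, ct = NULL) {
  if (!(kappa > 0)) stopf("kappa must be > 0")
  if (!(pl >= 0 && pl < pt && pt < pu && pu <= 1)) {
    stopf("require 0 <= pl < pt < pu <= 1 (got pl=%g, pt=%g, pu=%g)", pl, pt, pu)
  }
  s <- dynamic_range(pl, pu)
  pr <- (pt - pl) / s
  if (!(pr > 0 && pr < 1)) stopf("pt must lie strictly inside the dynamic range")
  structure(list(kappa = kappa, pl = pl, pu = pu, pt = pt, s = s, pr = pr, ct = ct),
            class = "crf_spec")
}

#' @export
print.crf_spec <- function(x, ...) {
  cat(sprintf("Logistic CRF: kappa=%g, pl=%g, pu=%g, pt=%g (s=%g, pr=%g)\n",
              x$kappa, x$pl, x$pu, x$pt, x$s, x$pr))
  invisible(x)
}

#' Dynamic range of the CRF
#'
#' `s = 1 - (1 - pu) - pl`, the probability mass spanned between the
#' guessing and lapse asymptotes.
#'
#' @param pl,pu Lower and upper asymptotes, `0 <= pl < pu <= 1`.
#' @return The dynamic range.
#' @export
dynamic_range <- function(pl, pu) {
  if (any(pl < 0) || any(pu > 1) || any(pl >= pu)) {
    stopf("require 0 <= pl < pu <= 1")
  }
  1 - (1 - pu) - pl
}

#' Threshold transformation for exact performance targeting
#'
#' Shifts the log10 threshold `ct` so that the logistic CRF evaluates to
#' exactly `pt` at `c = ct`:
#' \deqn{t = c_t - \kappa^{-1} \log\left(\frac{p_r}{1 - p_r}\right)}
#' with \eqn{p_r = (p_t - p_l)/s} and the natural logarithm (the
#' logistic's own base; any other base breaks the targeting identity).
#'
#' @param ct Log10 contrast threshold (vectorised).
#' @param spec A [crf_spec()].
#' @return The shifted logistic midpoint `t` in log10 contrast.
#' @export
threshold_transform <- function(ct, spec = crf_spec()) {
  stopifnot(inherits(spec, "crf_spec"))
  ct - log(spec$pr / (1 - spec$pr)) / spec$kappa
}

#' CRF probability of a correct response
#'
#' @param c Log10 contrast (vectorised).
#' @param spec A [crf_spec()].
#' @param ct Log10 contrast threshold; defaults to `spec$ct`.
#' @return Probability of a correct response, in `(pl, pl + s)`.
#' @examples
#' crf_probability(-1, crf_spec(), ct = -1) # exactly 0.75
#' @export
crf_probability <- function(c, spec = crf_spec(), ct = spec$ct) {
  stopifnot(inherits(spec, "crf_spec"))
  if (is.null(ct)) stopf("a threshold ct is required (in spec or as argument)")
  t <- threshold_transform(ct, spec)
  # exp() overflow at very low contrast gives Inf -> p == pl, as intended
  spec$s / (1 + exp(-spec$kappa * (c - t))) + spec$pl
}

#' Sample Bernoulli responses
#'
#' Draws binary correct/incorrect responses from the current R random
#' stream; wrap in a seeded context for reproducibility.
#'
#' @param p Probability (or vector of probabilities) of a correct response.
#' @param n Number of draws; defaults to `length(p)`.
#' @return Integer vector of 0/1 responses.
#' @export
sample_response <- function(p, n = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stopf("p must lie in [0, 1]")
  }
  rbinom(n, 1L, p)
}
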