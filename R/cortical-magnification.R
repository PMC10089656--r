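#' Meridian-specific linear cortical magnification
#'
#' Linear cortical magnification M(E) describes how many millimetres of
#' primary visual cortex represent one degree of visual angle at
#' eccentricity E along a given half meridian. It follows the classic
#' group-level form
#' \deqn{M(E) = M_0 (1 + aE + bE^3)^{-1}}
#' with meridian-specific coefficients for the nasal, temporal, lower
#' vertical (LVM) and upper vertical (UVM) meridians, and a foveal
#' magnification \code{M0} of 7.99 mm/degree by default.
#'
#' @param meridian One of `"nasal"`, `"temporal"`, `"LVM"`, `"UVM"`.
#' @param M0 Foveal magnification in mm per degree (default 7.99).
#' @param a Linear eccentricity coefficient (per degree). Defaults to the
#'   published value for `meridian`.
#' @param b Cubic eccentricity coefficient (per degree^3). Defaults to the
#'   published value for `meridian`.
#' @return An object of class `"magnification_model"`.
#' @examples
#' m <- magnification_model("LVM")
#' magnification(m, 6)
#' @export
magnification_model <- function(meridian = c("nasal", "temporal", "LVM", "UVM"),
                                M0 = 7.99, a = NULL, b = NULL) {
  meridian <- match.arg(meridian)
  coefs <- list(
    nasal    = c(a = 0.33, b = 0.00007),
    temporal = c(a = 0.29, b = 0.000012),
    LVM      = c(a = 0.42, b = 0.000055),
    UVM      = c(a = 0.42, b = 0.00012)
  )[[meridian]]
  a <- a %||% unname(coefs["a"])
  b <- b %||% unname(coefs["b"])
  if (!is.numeric(M0) || M0 <= 0) stopf("M0 must be positive (got %s)", M0)
  if (a <= 0 || b < 0) stopf("require a > 0 and b >= 0")
  structure(list(meridian = meridian, M0 = M0, a = a, b = b),
            class = "magnification_model")
}

#' @export
print.magnification_model <- function(x, ...) {
  cat(sprintf("Cortical magnification model [%s]: M(E) = %.2f / (1 + %g E + %g E^3) mm/deg\n",
              x$meridian, x$M0, x$a, x$b))
  invisible(x)
}

#' Evaluate cortical magnification at an eccentricity
#'
#' @param model A [magnification_model()].
#' @param E Eccentricity in degrees, non-negative (vectorised).
#' @return Magnification in mm per degree.
#' @export
magnification <- function(model, E) {
  stopifnot(inherits(model, "magnification_model"))
  if (any(!is.finite(E)) || any(E < 0)) {
    stopf("eccentricity must be finite and >= 0")
  }
  model$M0 / (1 + model$a * E + model$b * E^3)
}

# The four published meridian models at a common M0.
default_magnification_models <- function(M0 = 7.99) {
  mers <- c("nasal", "temporal", "LVM", "UVM")
  setNames(lapply(mers, magnification_model, M0 = M0), mers)
}

#' M-scaled stimulus size
#'
#' Computes the size a stimulus must take at a target eccentricity so that
#' its linear cortical representation matches that of a base stimulus at a
#' base eccentricity on the same meridian:
#' \deqn{S_b = S_a \, M(E_a) / M(E_b).}
#' The horizontal meridian (HM) has no single magnification equation; its
#' scaled size is the mean of the nasal-scaled and temporal-scaled sizes.
#'
#' The returned size is full precision; round at the reporting layer (the
#' conventional presentation is two decimals).
#'
#' @param meridian `"HM"`, `"LVM"` or `"UVM"`.
#' @param base_size Stimulus diameter in degrees at `base_ecc` (> 0).
#' @param base_ecc,target_ecc Eccentricities in degrees (>= 0).
#' @param M0 Foveal magnification passed to the default models.
#' @param models Optional named list of [magnification_model()]s; must
#'   contain `LVM` and `UVM`, plus `nasal` and `temporal` for the HM.
#' @return Scaled size in degrees of visual angle.
#' @examples
#' mscaled_size("LVM", 4, 2, 6) # ~7.68 deg
#' @export
mscaled_size <- function(meridian, base_size, base_ecc, target_ecc,
                         M0 = 7.99, models = default_magnification_models(M0)) {
  allowed <- c("HM", "LVM", "UVM")
  if (length(meridian) != 1 || !meridian %in% allowed) {
    stopf("unknown meridian '%s'; allowed: %s", paste(meridian, collapse = ","),
          paste(allowed, collapse = ", "))
  }
  if (!is.numeric(base_size) || base_size <= 0) stopf("base_size must be > 0")
  if (base_ecc < 0 || target_ecc < 0) stopf("eccentricities must be >= 0")
  scale_one <- function(m) base_size * magnification(m, base_ecc) / magnification(m, target_ecc)
  if (meridian == "HM") {
    if (is.null(models$nasal) || is.null(models$temporal)) {
      stopf("HM scaling needs both 'nasal' and 'temporal' models")
    }
    mean(c(scale_one(models$nasal), scale_one(models$temporal)))
  } else {
    if (is.null(models[[meridian]])) stopf("missing model for meridian '%s'", meridian)
    scale_one(models[[meridian]])
  }
}

#' Table of M-scaled sizes for several meridians
#'
#' Convenience reporting wrapper around [mscaled_size()]; sizes are also
#' given rounded to two decimals, the conventional print precision.
#'
#' @inheritParams mscaled_size
#' @param meridians Character vector of meridian labels.
#' @return A data frame with one row per meridian.
#' @export
mscale_table <- function(meridians = c("HM", "LVM", "UVM"), base_size = 4,
                         base_ecc = 2, target_ecc = 6, M0 = 7.99) {
  size <- vapply(meridians, mscaled_size, numeric(1),
                 base_size = base_size, base_ecc = base_ecc,
                 target_ecc = target_ecc, M0 = M0)
  data.frame(meridian = meridians, base_size = base_size, base_ecc = base_ecc,
             target_ecc = target_ecc, scaled_size = unname(size),
             scaled_size_2dp = round(unname(size), 2), row.names = NULL)
}
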