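#' Symmetric percent change between two locations
#'
#' The extent of a location effect is the difference in contrast
#' sensitivity normalised by the mean across the two locations:
#' \deqn{\Delta = 100 \frac{l_1 - l_2}{0.5 (l_1 + l_2)}}
#' Bounded in (-200, 200) and antisymmetric in its arguments.
#'
#' @param l1,l2 Positive sensitivities (vectorised).
#' @return Percent change; positive when `l1 > l2`.
#' @export
percent_change <- function(l1, l2) {
  if (any(l1 <= 0) || any(l2 <= 0)) stopf("sensitivities must be > 0")
  100 * (l1 - l2) / (0.5 * (l1 + l2))
}

#' Horizontal-vertical anisotropy extent
#'
#' Percent change between the HM and the vertical meridian (mean of LVM
#' and UVM); positive values mean an HM advantage.
#'
#' @param cs_hm,cs_lvm,cs_uvm Positive sensitivities (vectorised).
#' @return HVA extent in percent.
#' @export
hva_extent <- function(cs_hm, cs_lvm, cs_uvm) {
  percent_change(cs_hm, (cs_lvm + cs_uvm) / 2)
}

#' Vertical meridian asymmetry extent
#'
#' Percent change between LVM and UVM; positive values mean an LVM
#' advantage.
#'
#' @param cs_lvm,cs_uvm Positive sensitivities (vectorised).
#' @return VMA extent in percent.
#' @export
vma_extent <- function(cs_lvm, cs_uvm) {
  percent_change(cs_lvm, cs_uvm)
}

#' Asymmetry magnitude (reference-denominator percent increase)
#'
#' For CSF attribute summaries the asymmetry magnitude is the percent
#' increase relative to a reference location:
#' `100 * (other - ref) / ref`, with the VM (mean of LVM and UVM) as
#' reference for the HVA and the UVM as reference for the VMA. Note this
#' differs from [percent_change()] (whose denominator is the mean), and
#' that positive values mean the non-reference location is larger; the
#' sign convention is kept as stated rather than silently flipped.
#'
#' @param attr_ref Attribute value at the reference location (> 0).
#' @param attr_other Attribute value at the other location.
#' @return Percent increase from reference.
#' @export
asymmetry_magnitude <- function(attr_ref, attr_other) {
  if (any(attr_ref <= 0)) stopf("reference attribute must be > 0")
  100 * (attr_other - attr_ref) / attr_ref
}

#' Asymmetry table from per-cell sensitivities
#'
#' Computes, per spatial frequency (or per attribute), the eccentricity
#' effect (2 vs 6 degrees, and 2 vs 6 M-scaled when present), the HVA
#' extent at each eccentricity, and the VMA extent at each eccentricity,
#' all via the symmetric percent change.
#'
#' @param cs Data frame with columns `angle`, `ecc`, `scaled`, `value`
#'   and a key column (`sf` or `attribute`) named by `by`.
#' @param by Name of the key column (default `"sf"`).
#' @return Long data frame with columns `comparison`, the key, and
#'   `pct_change`.
#' @export
asymmetry_table <- function(cs, by = "sf") {
  req <- c("angle", "ecc", "scaled", "value", by)
  if (!all(req %in% names(cs))) {
    stopf("cs needs columns: %s", paste(req, collapse = ", "))
  }
  keys <- unique(cs[[by]])
  rows <- list()
  get <- function(key, angle, ecc, scaled) {
    v <- cs$value[cs[[by]] == key & cs$angle == angle &
                    cs$ecc == ecc & cs$scaled == scaled]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  for (key in keys) {
    hm2 <- get(key, "HM", 2, FALSE); hm6 <- get(key, "HM", 6, FALSE)
    lv2 <- get(key, "LVM", 2, FALSE); lv6 <- get(key, "LVM", 6, FALSE)
    uv2 <- get(key, "UVM", 2, FALSE); uv6 <- get(key, "UVM", 6, FALSE)
    hm6m <- get(key, "HM", 6, TRUE); lv6m <- get(key, "LVM", 6, TRUE)
    uv6m <- get(key, "UVM", 6, TRUE)
    avg <- function(...) mean(c(...), na.rm = TRUE)
    m2 <- avg(hm2, lv2, uv2); m6 <- avg(hm6, lv6, uv6)
    m6m <- avg(hm6m, lv6m, uv6m)
    add <- function(comp, val) {
      rows[[length(rows) + 1L]] <<- data.frame(comparison = comp, key = key,
                                               pct_change = val)
    }
    if (is.finite(m2) && is.finite(m6)) add("ecc 2v6", percent_change(m2, m6))
    if (is.finite(m2) && is.finite(m6m)) add("ecc 2v6M", percent_change(m2, m6m))
    if (all(is.finite(c(hm2, lv2, uv2)))) add("HVA 2", hva_extent(hm2, lv2, uv2))
    if (all(is.finite(c(hm6, lv6, uv6)))) add("HVA 6", hva_extent(hm6, lv6, uv6))
    if (all(is.finite(c(hm6m, lv6m, uv6m)))) add("HVA 6M", hva_extent(hm6m, lv6m, uv6m))
    if (all(is.finite(c(lv2, uv2)))) add("VMA 2", vma_extent(lv2, uv2))
    if (all(is.finite(c(lv6, uv6)))) add("VMA 6", vma_extent(lv6, uv6))
    if (all(is.finite(c(lv6m, uv6m)))) add("VMA 6M", vma_extent(lv6m, uv6m))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "key"] <- by
  out
}
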