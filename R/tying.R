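#' Visual-field location cells
#'
#' The experiment places gratings at the crossing of two eccentricities
#' (2 and 6 degrees) and three polar angles: horizontal meridian (HM,
#' left/right pooled), lower vertical meridian (LVM) and upper vertical
#' meridian (UVM). M-scaled stimuli form additional 6-degree cells with
#' `scaled = TRUE`.
#'
#' @param eccs Eccentricities in degrees.
#' @param angles Polar-angle labels among `"HM"`, `"LVM"`, `"UVM"`.
#' @param scaled Logical flag for the M-scaled condition.
#' @return A data frame with columns `angle`, `ecc`, `scaled` and the
#'   canonical `cell` id label.
#' @export
location_cells <- function(eccs = c(2, 6), angles = c("HM", "LVM", "UVM"),
                           scaled = FALSE) {
  stopifnot(all(angles %in% c("HM", "LVM", "UVM")))
  g <- expand.grid(angle = angles, ecc = eccs, scaled = scaled,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$cell <- cell_id(g$angle, g$ecc, g$scaled)
  g
}

cell_id <- function(angle, ecc, scaled) {
  paste0(angle, "_", format(ecc, trim = TRUE),
         ifelse(scaled, "_Mscale", ""))
}

#' Parameter-tying models across the visual field
#'
#' Builds the partition of the six fixed-size location cells into groups
#' of shared CSF parameters, controlled by three flags:
#' \describe{
#'   \item{ecc}{off: 2 and 6 degrees share parameters.}
#'   \item{hva}{off: the HM shares parameters with the LVM.}
#'   \item{vma}{off: the UVM shares parameters with the LVM.}
#' }
#' The free-parameter count is `k = (parameters per CSF form) x (number
#' of groups)`, with group count
#' `(ecc ? 2 : 1) * (3 - (hva ? 0 : 1) - (vma ? 0 : 1))`.
#' M-scaled cells, when supplied, are never tied: each gets its own group
#' (the tying family is defined over the fixed-size conditions).
#'
#' @param ecc,hva,vma Logical flags enabling eccentricity, horizontal-
#'   vertical, and vertical-meridian parameter differences.
#' @param csf_model CSF form label, fixing the parameters per group.
#' @param cells Data frame of cells as from [location_cells()]; defaults
#'   to the six fixed-size cells.
#' @return An object of class `"vf_model"` with fields `ecc`, `hva`,
#'   `vma`, `partition` (named map cell id -> group id), `n_groups`, `k`
#'   and `label` (e.g. `"+Ecc +HVA -VMA"`).
#' @examples
#' build_tying(TRUE, TRUE, TRUE, "DoG")$k  # 24
#' @export
build_tying <- function(ecc = TRUE, hva = TRUE, vma = TRUE,
                        csf_model = "LP", cells = location_cells()) {
  csf_model <- match.arg(csf_model, csf_models())
  stopifnot(is.logical(ecc), is.logical(hva), is.logical(vma))
  fixed <- cells[!cells$scaled, , drop = FALSE]
  scaledc <- cells[cells$scaled, , drop = FALSE]

  angle_group <- function(angle) {
    # HVA off: HM folds into LVM; VMA off: UVM folds into LVM
    a <- angle
    a[!hva & a == "HM"] <- "LVM"
    a[!vma & a == "UVM"] <- "LVM"
    a
  }
  ecc_group <- if (ecc) format(fixed$ecc, trim = TRUE) else "all"
  grp <- paste0("e", ecc_group, ":", angle_group(fixed$angle))
  partition <- setNames(grp, fixed$cell)
  if (nrow(scaledc) > 0) {
    partition <- c(partition, setNames(paste0("own:", scaledc$cell), scaledc$cell))
  }
  n_groups <- length(unique(partition))
  structure(list(
    ecc = ecc, hva = hva, vma = vma,
    csf_model = csf_model,
    partition = partition,
    n_groups = n_groups,
    k = n_csf_params(csf_model) * n_groups,
    label = paste0(ifelse(ecc, "+", "-"), "Ecc ",
                   ifelse(hva, "+", "-"), "HVA ",
                   ifelse(vma, "+", "-"), "VMA")
  ), class = "vf_model")
}

#' @export
print.vf_model <- function(x, ...) {
  cat(sprintf("Visual-field model %s [%s]: %d group(s), k = %d\n",
              x$label, x$csf_model, x$n_groups, x$k))
  invisible(x)
}

#' All six tying models
#'
#' The model family: every combination of the eccentricity, HVA and VMA
#' flags that appears in the comparison set (the two single-asymmetry
#' models with `ecc` on, plus the full, no-ecc, no-asymmetry and null
#' models).
#'
#' @inheritParams build_tying
#' @return A named list of six [build_tying()] objects.
#' @export
vf_model_family <- function(csf_model = "LP", cells = location_cells()) {
  flags <- list(
    c(TRUE,  TRUE,  TRUE),
    c(TRUE,  TRUE,  FALSE),
    c(TRUE,  FALSE, TRUE),
    c(FALSE, TRUE,  TRUE),
    c(TRUE,  FALSE, FALSE),
    c(FALSE, FALSE, FALSE)
  )
  out <- lapply(flags, function(fl) {
    build_tying(fl[1], fl[2], fl[3], csf_model = csf_model, cells = cells)
  })
  setNames(out, vapply(out, `[[`, character(1), "label"))
}
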