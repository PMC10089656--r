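#' Ground-truth synthetic observer
#'
#' Builds an observer whose per-location CSFs embed a configurable
#' eccentricity effect and polar-angle asymmetries. Asymmetries scale the
#' gain `delta` of a base CSF (optionally also its peak frequency
#' `alpha`) so that the symmetric percent-change statistic
#' (see [percent_change()]) computed on the true peak sensitivities
#' equals the requested knob values exactly:
#' \itemize{
#'   \item `hva_pct`: percent change between the HM and the mean of LVM
#'     and UVM, at each eccentricity.
#'   \item `vma_pct`: percent change between LVM and UVM.
#'   \item `ecc_drop`: fractional sensitivity loss from 2 to 6 degrees
#'     (`s6 = (1 - ecc_drop) * s2`), applied uniformly across angles.
#' }
#' M-scaled 6-degree cells keep the angular asymmetries but have the
#' eccentricity loss removed in proportion `mscale_recovery` (default 1:
#' full removal, the empirical signature of cortical magnification
#' driving the eccentricity effect but not the polar-angle asymmetries).
#'
#' Presets: `"paper-like"` (`ecc_drop = 0.4`, `hva_pct = 40`,
#' `vma_pct = 20`), `"null"` (all zero), `"no-vma"` (`hva_pct = 40`,
#' `vma_pct = 0`, `ecc_drop = 0.4`).
#'
#' @param scenario Preset label, or `NULL` to use the explicit knobs.
#' @param ecc_drop Fractional loss in `[0, 1)` from 2 to 6 degrees.
#' @param hva_pct,vma_pct Asymmetry knobs in percent, inside (-100, 100).
#' @param base A [csf_params()] giving the grand-mean CSF (default log
#'   parabola, `alpha = 2` cpd, `beta = 1.2` octaves, `delta = 80`).
#' @param crf A [crf_spec()].
#' @param alpha_coupling Exponent coupling the per-cell gain multiplier
#'   into `alpha` (0 = pure gain asymmetries; > 0 also shifts peak/cutoff
#'   frequency).
#' @param mscale_recovery Fraction of the eccentricity loss removed in
#'   the M-scaled cells.
#' @param id Observer id string.
#' @return An object of class `"csf_observer"` with `$cells`, `$params`
#'   (per-cell [csf_params()]), `$crf` and the knob settings.
#' @examples
#' ob <- make_observer("paper-like")
#' sapply(ob$params, function(p) p$delta)
#' @export
make_observer <- function(scenario = NULL, ecc_drop = 0, hva_pct = 0,
                          vma_pct = 0,
                          base = csf_params("LP", alpha = 2, beta = 1.2, delta = 80),
                          crf = crf_spec(), alpha_coupling = 0,
                          mscale_recovery = 1, id = "obs1") {
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("paper-like", "null", "no-vma"))
    knobs <- switch(scenario,
      "paper-like" = list(ecc_drop = 0.4, hva_pct = 40, vma_pct = 20),
      "null"       = list(ecc_drop = 0, hva_pct = 0, vma_pct = 0),
      "no-vma"     = list(ecc_drop = 0.4, hva_pct = 40, vma_pct = 0)
    )
    ecc_drop <- knobs$ecc_drop; hva_pct <- knobs$hva_pct; vma_pct <- knobs$vma_pct
  }
  if (abs(hva_pct) >= 100 || abs(vma_pct) >= 100) {
    stopf("asymmetry knobs must lie inside (-100, 100) percent")
  }
  if (ecc_drop < 0 || ecc_drop >= 1) stopf("ecc_drop must be in [0, 1)")
  stopifnot(inherits(base, "csf_params"), inherits(crf, "crf_spec"))

  # invert the symmetric percent change: x/y = (200 + P) / (200 - P)
  rho_h <- (200 + hva_pct) / (200 - hva_pct)
  rho_v <- (200 + vma_pct) / (200 - vma_pct)
  # normalise so mean(HM, mean(LVM, UVM)) equals the eccentricity scale
  vmbar <- 2 / (1 + rho_h)
  ang <- c(HM = rho_h * vmbar,
           LVM = 2 * vmbar * rho_v / (1 + rho_v),
           UVM = 2 * vmbar / (1 + rho_v))

  cells <- rbind(location_cells(eccs = c(2, 6)),
                 location_cells(eccs = 6, scaled = TRUE))
  ecc_scale <- function(ecc, scaled) {
    s2 <- 1; s6 <- 1 - ecc_drop
    ifelse(ecc == 2, s2,
           ifelse(scaled, s6 + mscale_recovery * (s2 - s6), s6))
  }
  mult <- unname(ang[cells$angle]) * ecc_scale(cells$ecc, cells$scaled)
  params <- lapply(seq_len(nrow(cells)), function(i) {
    csf_params(base$model,
               alpha = base$alpha * mult[i]^alpha_coupling,
               beta = base$beta, gamma = base$gamma,
               delta = base$delta * mult[i])
  })
  names(params) <- cells$cell
  structure(list(id = id, cells = cells, params = params, crf = crf,
                 knobs = list(ecc_drop = ecc_drop, hva_pct = hva_pct,
                              vma_pct = vma_pct,
                              alpha_coupling = alpha_coupling,
                              mscale_recovery = mscale_recovery),
                 base = base),
            class = "csf_observer")
}

#' @export
print.csf_observer <- function(x, ...) {
  cat(sprintf("Synthetic observer '%s': %d cells, knobs ecc_drop=%g hva=%g%% vma=%g%%\n",
              x$id, nrow(x$cells), x$knobs$ecc_drop, x$knobs$hva_pct, x$knobs$vma_pct))
  invisible(x)
}

#' Experiment design
#'
#' Describes which cells are measured under which condition, the
#' titration procedure and the per-SF trial count. The default mirrors
#' the reference design: fixed-size HM condition at 2 and 6 degrees with
#' a weighted staircase (160 trials per SF per location), fixed-size VM
#' condition (LVM/UVM, best PEST, 140 per SF), and an M-scaled
#' 6-degree condition at all three angles (best PEST, 84 per SF), with
#' spatial frequencies 0.5-11.3 cpd in half-octave-ish steps.
#'
#' @param sfs Spatial frequencies in cpd.
#' @param conditions Data frame with columns `condition`, `angle`, `ecc`,
#'   `scaled`, `procedure`, `trials_per_sf`; `NULL` gives the default.
#' @return An object of class `"experiment_design"`.
#' @export
experiment_design <- function(sfs = c(0.5, 1, 1.4, 2, 2.8, 4, 8, 11.3),
                              conditions = NULL) {
  if (any(sfs <= 0) || anyDuplicated(sfs)) stopf("SFs must be positive and unique")
  if (is.null(conditions)) {
    conditions <- rbind(
      data.frame(condition = "HM", angle = "HM", ecc = c(2, 6), scaled = FALSE,
                 procedure = "staircase", trials_per_sf = 160L),
      expand.grid(condition = "VM", angle = c("LVM", "UVM"), ecc = c(2, 6),
                  scaled = FALSE, procedure = "pest", trials_per_sf = 140L,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
      data.frame(condition = "M-scale", angle = c("HM", "LVM", "UVM"), ecc = 6,
                 scaled = TRUE, procedure = "pest", trials_per_sf = 84L)
    )
  }
  req <- c("condition", "angle", "ecc", "scaled", "procedure", "trials_per_sf")
  if (!all(req %in% names(conditions))) {
    stopf("conditions needs columns: %s", paste(req, collapse = ", "))
  }
  if (any(conditions$trials_per_sf < 1)) stopf("trial counts must be positive")
  conditions$cell <- cell_id(conditions$angle, conditions$ecc, conditions$scaled)
  structure(list(sfs = sort(sfs), conditions = conditions),
            class = "experiment_design")
}

#' Simulate a full experiment
#'
#' Runs the configured adaptive titration independently for every
#' (cell, SF) combination of the design against a ground-truth observer,
#' then randomly interleaves the per-track trial sequences (order within
#' each track is preserved, as the adaptive procedures are sequential).
#'
#' @param observer A [make_observer()] observer.
#' @param design An [experiment_design()].
#' @param seed Master integer seed; the full table is reproducible.
#' @return A tidy trial data frame with columns `observer`, `condition`,
#'   `angle`, `ecc`, `scaled`, `cell`, `sf`, `log10_contrast`,
#'   `response`, `trial` (interleaved presentation index) and
#'   `trial_in_track`.
#' @export
simulate_experiment <- function(observer, design = experiment_design(), seed = 1L) {
  stopifnot(inherits(observer, "csf_observer"), inherits(design, "experiment_design"))
  missing_cells <- setdiff(design$conditions$cell, names(observer$params))
  if (length(missing_cells) > 0) {
    stopf("design references cell(s) absent from observer: %s",
          paste(missing_cells, collapse = ", "))
  }
  tracks <- merge(design$conditions, data.frame(sf = design$sfs), by = NULL)
  seeds <- derive_seeds(seed, nrow(tracks) + 1L)
  out <- vector("list", nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    tr <- tracks[i, ]
    run <- run_titration(observer, procedure = tr$procedure, cell = tr$cell,
                         f = tr$sf, n_trials = tr$trials_per_sf,
                         seed = seeds[i])
    out[[i]] <- data.frame(
      observer = observer$id, condition = tr$condition, angle = tr$angle,
      ecc = tr$ecc, scaled = tr$scaled, cell = tr$cell, sf = tr$sf,
      log10_contrast = run$trials$log10_contrast,
      response = run$trials$response,
      trial_in_track = run$trials$trial,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  # random interleave preserving within-track order: shuffle the
  # sequence of track labels, then fill each track's trials in order
  stream <- rep(seq_len(nrow(tracks)), times = tracks$trials_per_sf)
  ord <- with_seed(seeds[nrow(tracks) + 1L], sample(length(stream)))
  slot <- integer(length(stream))
  shuffled <- stream[ord]
  pos <- split(seq_along(shuffled), shuffled)
  row_of <- split(seq_len(nrow(tab)), rep(seq_len(nrow(tracks)), times = tracks$trials_per_sf))
  for (k in seq_len(nrow(tracks))) slot[pos[[as.character(k)]]] <- row_of[[as.character(k)]]
  tab <- tab[slot, , drop = FALSE]
  tab$trial <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' Titration-based threshold estimates per cell and SF
#'
#' Convenience wrapper: runs the design and returns, per (cell, SF), the
#' procedure's threshold estimate and the implied sensitivity, alongside
#' the ground truth.
#'
#' @inheritParams simulate_experiment
#' @return Data frame with one row per (cell, SF).
#' @export
titration_estimates <- function(observer, design = experiment_design(), seed = 1L) {
  stopifnot(inherits(observer, "csf_observer"), inherits(design, "experiment_design"))
  tracks <- merge(design$conditions, data.frame(sf = design$sfs), by = NULL)
  seeds <- derive_seeds(seed, nrow(tracks) + 1L)
  res <- lapply(seq_len(nrow(tracks)), function(i) {
    tr <- tracks[i, ]
    run <- run_titration(observer, procedure = tr$procedure, cell = tr$cell,
                         f = tr$sf, n_trials = tr$trials_per_sf, seed = seeds[i])
    data.frame(cell = tr$cell, angle = tr$angle, ecc = tr$ecc,
               scaled = tr$scaled, sf = tr$sf,
               estimate_ct = run$estimate, true_ct = run$true_ct,
               sensitivity = 10^(-run$estimate),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
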