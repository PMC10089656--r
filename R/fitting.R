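#' Trial-wise negative log-likelihood
#'
#' Each trial is an independent Bernoulli observation whose success
#' probability comes from the logistic CRF evaluated at the trial's
#' log10 contrast, with threshold `ct(f, cell) = -log10(S(f))` where `S`
#' is the CSF of the trial's tied parameter group.
#'
#' @param trials Trial data frame with columns `cell`, `sf`,
#'   `log10_contrast`, `response` (0/1).
#' @param params Named list mapping group id to [csf_params()].
#' @param partition Named map cell id -> group id (e.g.
#'   `build_tying(...)$partition`).
#' @param crf A [crf_spec()].
#' @return The negative log-likelihood in nats (additive over trials).
#' @export
negative_log_likelihood <- function(trials, params, partition, crf = crf_spec()) {
  check_trials(trials)
  unknown <- setdiff(unique(trials$cell), names(partition))
  if (length(unknown) > 0) {
    stopf("trials reference unknown cell(s) %s; known: %s",
          paste(unknown, collapse = ", "), paste(names(partition), collapse = ", "))
  }
  grp <- partition[trials$cell]
  missing_par <- setdiff(unique(grp), names(params))
  if (length(missing_par) > 0) {
    stopf("no parameters for group(s): %s", paste(missing_par, collapse = ", "))
  }
  nll <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    nll <- nll + nll_group(trials$log10_contrast[idx], trials$sf[idx],
                           trials$response[idx], params[[g]], crf)
  }
  nll
}

# Vectorised single-group negative log-likelihood.
nll_group <- function(c, f, y, params, crf) {
  s <- csf_sensitivity(params, f)
  ct <- -log10(pmax(s, .Machine$double.xmin))
  p <- crf_probability(c, crf, ct = ct)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Optimizer options for CSF fitting
#'
#' Bounded quasi-Newton (`L-BFGS-B`) with seeded multistarts; positive
#' parameters are searched in log10 space. Bounds come from the
#' per-model defaults (see the methods vignette).
#'
#' @param n_starts Number of multistarts per parameter group (default 20).
#' @param seed Integer seed controlling the random starts.
#' @param maxit Maximum iterations per start.
#' @return A list of options for [fit_model()].
#' @export
fit_opts <- function(n_starts = 20L, seed = 1L, maxit = 300L) {
  list(n_starts = as.integer(n_starts), seed = as.integer(seed),
       maxit = as.integer(maxit))
}

# theta <-> csf_params transforms. alpha/beta/delta log10; gamma linear
# (MS beta is linear too since its lower bound may be 0).
param_transform <- function(model) {
  b <- csf_bounds(model)
  nm <- names(b)
  log_scaled <- vapply(nm, function(p) b[[p]][1] > 0, logical(1))
  list(names = nm, bounds = b, log_scaled = log_scaled)
}

theta_to_params <- function(theta, model, tr = param_transform(model)) {
  vals <- ifelse(tr$log_scaled, 10^theta, theta)
  names(vals) <- tr$names
  csf_params(model,
             alpha = vals[["alpha"]], beta = vals[["beta"]],
             gamma = if ("gamma" %in% tr$names) vals[["gamma"]] else NA_real_,
             delta = vals[["delta"]])
}

#' Fit a CSF / visual-field model to trial data
#'
#' Maximum-likelihood fit of one CSF functional form across location
#' cells under a tying model. Because each trial belongs to exactly one
#' tied group, the likelihood factorises over groups and each group is
#' optimised independently (the summed optimum is the joint optimum).
#'
#' @param trials Trial data frame (see [negative_log_likelihood()]).
#' @param csf_model CSF form label.
#' @param vf_spec A `"vf_model"` from [build_tying()], or `NULL` for the
#'   most permissive tying over the cells present in `trials`.
#' @param crf A [crf_spec()].
#' @param opts Optimizer options from [fit_opts()].
#' @return An object of class `"csf_fit"`: per-group parameters,
#'   log-likelihood, `k`, `n`, `bic`, convergence metadata, and the
#'   tying specification.
#' @export
fit_model <- function(trials, csf_model = "LP", vf_spec = NULL,
                      crf = crf_spec(), opts = fit_opts()) {
  csf_model <- match.arg(csf_model, csf_models())
  check_trials(trials)
  if (is.null(vf_spec)) {
    cells <- unique(trials[, c("angle", "ecc", "scaled")])
    cells$cell <- cell_id(cells$angle, cells$ecc, cells$scaled)
    vf_spec <- build_tying(TRUE, TRUE, TRUE, csf_model = csf_model, cells = cells)
  }
  if (vf_spec$csf_model != csf_model) {
    vf_spec <- build_tying(vf_spec$ecc, vf_spec$hva, vf_spec$vma,
                           csf_model = csf_model,
                           cells = partition_cells(vf_spec$partition))
  }
  partition <- vf_spec$partition
  unknown <- setdiff(unique(trials$cell), names(partition))
  if (length(unknown) > 0) {
    stopf("trials reference cell(s) outside the tying model: %s",
          paste(unknown, collapse = ", "))
  }
  grp <- partition[trials$cell]
  groups <- unique(partition)
  groups <- groups[groups %in% grp]   # cells without data drop out
  tr <- param_transform(csf_model)
  seeds <- derive_seeds(opts$seed, length(groups))

  params <- list(); conv <- list(); total_nll <- 0
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    idx <- which(grp == g)
    res <- fit_group(trials$log10_contrast[idx], trials$sf[idx],
                     trials$response[idx], csf_model, tr, crf,
                     opts, seeds[gi])
    if (!res$ok) {
      stopf("optimizer failed on all %d starts for group '%s'", opts$n_starts, g)
    }
    params[[g]] <- res$params
    conv[[g]] <- res$meta
    total_nll <- total_nll + res$nll
  }
  n <- nrow(trials)
  k <- n_csf_params(csf_model) * length(groups)
  loglik <- -total_nll
  fit <- structure(list(
    csf_model = csf_model, vf_spec = vf_spec, params = params,
    loglik = loglik, k = k, n = n,
    bic = bic_value(k, n, loglik),
    convergence = conv,
    opts = opts,
    data_signature = trial_signature(trials)
  ), class = "csf_fit")
  fit
}

fit_group <- function(c, f, y, model, tr, crf, opts, seed) {
  lb <- vapply(tr$names, function(p) {
    v <- tr$bounds[[p]]
    if (tr$log_scaled[[p]]) log10(v[1]) else v[1]
  }, numeric(1))
  ub <- vapply(tr$names, function(p) {
    v <- tr$bounds[[p]]
    if (tr$log_scaled[[p]]) log10(v[2]) else v[2]
  }, numeric(1))
  obj <- function(theta) {
    pars <- try(theta_to_params(theta, model, tr), silent = TRUE)
    if (inherits(pars, "try-error")) return(1e10)
    v <- nll_group(c, f, y, pars, crf)
    if (!is.finite(v)) 1e10 else v
  }
  # deterministic starts (data-driven + midpoint) + seeded random starts
  mid <- (lb + ub) / 2
  dd <- data_start(c, f, y, model, tr)
  n_rand <- max(opts$n_starts - 2L, 0L)
  starts <- with_seed(seed, {
    rs <- matrix(runif(n_rand * length(lb),
                       rep(lb, each = n_rand),
                       rep(ub, each = n_rand)),
                 nrow = n_rand)
    rbind(dd, mid, rs)
  })
  starts <- sweep(starts, 2, lb, pmax)
  starts <- sweep(starts, 2, ub, pmin)
  best <- NULL; codes <- integer(0)
  for (si in seq_len(nrow(starts))) {
    res <- try(optim(starts[si, ], obj, method = "L-BFGS-B",
                     lower = lb, upper = ub,
                     control = list(maxit = opts$maxit)), silent = TRUE)
    if (inherits(res, "try-error")) next
    codes <- c(codes, res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    return(list(ok = FALSE))
  }
  list(ok = TRUE,
       params = theta_to_params(best$par, model, tr),
       nll = best$value,
       meta = list(n_starts = nrow(starts), seed = seed,
                   convergence_codes = codes, value = best$value))
}

# Data-driven start: titration concentrates placements near threshold,
# so per-SF mean contrast approximates ct(f); its inverse approximates
# the sensitivity profile, giving a rough peak location and gain.
data_start <- function(c, f, y, model, tr) {
  m <- tapply(c, f, mean)
  sens <- 10^(-m)
  F0 <- as.numeric(names(sens)[which.max(sens)])
  S0 <- max(sens)
  vals <- switch(model,
    LP   = c(alpha = F0, beta = 1.5, delta = S0),
    dEXP = c(alpha = 0.5, beta = 2 * F0, delta = S0 / (max(F0, 0.1)^0.5 * exp(-0.5))),
    aLP  = c(alpha = F0, beta = 1.5, gamma = 1.5, delta = S0),
    DoG  = c(alpha = 2 * F0, beta = F0 / 2, gamma = 0.5, delta = 2 * S0),
    YQM  = c(alpha = 3 * F0, beta = F0, gamma = 3, delta = 2 * S0),
    MS   = c(alpha = F0, beta = 0.5, gamma = 2, delta = S0),
    HmH  = c(alpha = 2 * F0, beta = F0 / 2, gamma = 0.5, delta = 2 * S0),
    HmG  = c(alpha = 2 * F0, beta = F0 / 2, gamma = 0.5, delta = 2 * S0),
    EmG  = c(alpha = 2 * F0, beta = F0 / 2, gamma = 0.5, delta = 2 * S0)
  )
  vapply(tr$names, function(p) {
    b <- tr$bounds[[p]]
    v <- min(max(vals[[p]], b[1]), b[2])
    if (tr$log_scaled[[p]]) log10(v) else v
  }, numeric(1))
}

# Reconstruct the cells data frame from a partition's names.
partition_cells <- function(partition) {
  ids <- names(partition)
  parts <- strsplit(ids, "_", fixed = TRUE)
  data.frame(
    angle = vapply(parts, `[[`, character(1), 1),
    ecc = as.numeric(vapply(parts, `[[`, character(1), 2)),
    scaled = vapply(parts, function(p) length(p) > 2, logical(1)),
    cell = ids, stringsAsFactors = FALSE
  )
}

# Cheap order-invariant signature used to refuse cross-dataset comparisons.
trial_signature <- function(trials) {
  c(n = nrow(trials), sy = sum(trials$response),
    sc = round(sum(trials$log10_contrast), 6),
    sf = round(sum(trials$sf), 6))
}

#' @export
print.csf_fit <- function(x, ...) {
  cat(sprintf("CSF fit [%s | %s]: n = %d trials, k = %d, logLik = %.2f, BIC = %.2f\n",
              x$csf_model, x$vf_spec$label, x$n, x$k, x$loglik, x$bic))
  invisible(x)
}

#' Per-cell parameters of a fit
#'
#' Maps each location cell to its tied group's fitted parameter object;
#' cells sharing a group return the identical object.
#'
#' @param fit A `"csf_fit"`.
#' @return Named list of [csf_params()] keyed by cell id.
#' @export
cell_params <- function(fit) {
  stopifnot(inherits(fit, "csf_fit"))
  part <- fit$vf_spec$partition
  part <- part[part %in% names(fit$params)]
  setNames(lapply(part, function(g) fit$params[[g]]), names(part))
}

bic_value <- function(k, n, loglik) k * log(n) - 2 * loglik

#' Bayesian information criterion of a fit
#'
#' `BIC = k ln(n) - 2 lnL`; lower is better.
#'
#' @param fit A `"csf_fit"`, or a numeric log-likelihood when `k` and `n`
#'   are given explicitly.
#' @param k,n Parameter and trial counts (used when `fit` is numeric).
#' @return The BIC value.
#' @export
bic <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "csf_fit")) return(bic_value(fit$k, fit$n, fit$loglik))
  if (is.null(k) || is.null(n)) stopf("supply k and n with a numeric loglik")
  if (n < 1) stopf("n must be >= 1")
  bic_value(k, n, fit)
}

#' Rank fitted models by BIC
#'
#' @param fits A list of `"csf_fit"` objects fitted to the same trials.
#' @return A data frame ranked by BIC with `delta_bic` relative to the
#'   best model; exact ties are broken toward the smaller `k`
#'   (parsimony). Stable under permutation of the input order.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "csf_fit")))
  sigs <- vapply(fits, function(f) paste(f$data_signature, collapse = "|"), character(1))
  if (length(unique(sigs)) > 1) {
    stopf("fits were computed on different trial sets; refusing to compare")
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$csf_model, character(1)),
    vf_model = vapply(fits, function(f) f$vf_spec$label, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    n = vapply(fits, function(f) f$n, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$bic, tab$k, tab$model, tab$vf_model)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_bic <- tab$bic - tab$bic[1]
  rownames(tab) <- NULL
  tab
}

#' Stage 1: rank CSF functional forms
#'
#' Fits each candidate CSF form to the trials under the most permissive
#' tying model (every fixed-size cell free; M-scaled cells their own
#' cells) and ranks the forms by BIC.
#'
#' @param trials Trial data frame (all conditions).
#' @param models CSF form labels to consider.
#' @inheritParams fit_model
#' @return List with `ranking` (from [compare_models()]), `fits`, and
#'   `best` (winning form label).
#' @export
select_csf_model <- function(trials, models = csf_models(),
                             crf = crf_spec(), opts = fit_opts()) {
  fits <- lapply(models, function(m) {
    fit_model(trials, csf_model = m, vf_spec = NULL, crf = crf, opts = opts)
  })
  names(fits) <- models
  ranking <- compare_models(fits)
  list(ranking = ranking, fits = fits, best = ranking$model[1])
}

#' Stage 2: rank visual-field tying models
#'
#' Fits the six tying models with a fixed CSF form to the fixed-size
#' trials only (the tying family is defined over the fixed-size
#' conditions) and ranks them by BIC.
#'
#' @param trials Trial data frame; M-scaled trials are dropped with a
#'   message if present.
#' @param csf_model The stage-1 winning CSF form.
#' @inheritParams fit_model
#' @return List with `ranking`, `fits`, and `best` (winning tying label).
#' @export
select_vf_model <- function(trials, csf_model, crf = crf_spec(),
                            opts = fit_opts()) {
  check_trials(trials)
  if (any(trials$scaled)) {
    message("dropping ", sum(trials$scaled),
            " M-scaled trials: tying models apply to fixed-size conditions")
    trials <- trials[!trials$scaled, , drop = FALSE]
  }
  family <- vf_model_family(csf_model = csf_model)
  fits <- lapply(family, function(vf) {
    fit_model(trials, csf_model = csf_model, vf_spec = vf, crf = crf, opts = opts)
  })
  ranking <- compare_models(fits)
  list(ranking = ranking, fits = fits, best = ranking$vf_model[1])
}
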