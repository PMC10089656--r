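#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject ANOVA for one or two factors, with
#' Greenhouse-Geisser (GG) epsilon and corrected p-values per effect, and
#' generalized eta squared effect sizes (denominator pooling the subject
#' variance and every within-subject error term).
#'
#' @param data Long-format data frame.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-subject factor
#'   column names.
#' @param subject Name of the subject id column.
#' @return A data frame (class `"rm_anova"`), one row per effect, with
#'   `df1`, `df2`, `F`, `p`, `eps_gg`, `df1_gg`, `df2_gg`, `p_gg`,
#'   `eta_g_sq`.
#' @export
rm_anova <- function(data, dv, within, subject) {
  stopifnot(length(within) %in% 1:2, all(c(dv, within, subject) %in% names(data)))
  data <- data[, c(subject, within, dv)]
  if (any(!complete.cases(data))) stopf("missing values in the design")
  for (w in within) data[[w]] <- factor(data[[w]])
  data[[subject]] <- factor(data[[subject]])
  # balanced, one observation per subject x cell
  cellkey <- interaction(data[c(subject, within)], drop = FALSE)
  counts <- table(cellkey)
  if (any(counts != 1)) {
    bad <- names(counts)[counts != 1]
    stopf("design must have exactly one observation per subject/cell; offending cells: %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }

  subj <- levels(data[[subject]])
  n <- length(subj)
  lev <- lapply(within, function(w) levels(data[[w]]))
  sizes <- vapply(lev, length, integer(1))
  # wide matrix: subjects x cells, cells ordered with factor 1 slowest
  ord <- do.call(order, c(data[c(subject)], data[within]))
  data <- data[ord, ]
  ncell <- prod(sizes)
  Y <- matrix(data[[dv]], nrow = n, ncol = ncell, byrow = TRUE)

  # orthonormal contrast basis for a factor with L levels
  onb <- function(L) {
    C <- stats::contr.helmert(L)
    qr.Q(qr(C))
  }
  ones <- function(L) matrix(1 / sqrt(L), nrow = L, ncol = 1)

  effects <- list()
  if (length(within) == 1L) {
    effects[[within[1]]] <- list(onb(sizes[1]))
  } else {
    effects[[within[1]]] <- list(onb(sizes[1]), ones(sizes[2]))
    effects[[within[2]]] <- list(ones(sizes[1]), onb(sizes[2]))
    effects[[paste(within, collapse = ":")]] <- list(onb(sizes[1]), onb(sizes[2]))
  }

  grand <- mean(Y)
  ss_subj <- ncell * sum((rowMeans(Y) - grand)^2)
  res <- list(); ss_err_all <- 0
  for (nm in names(effects)) {
    M <- Reduce(kronecker, effects[[nm]])      # cells x df basis
    Z <- Y %*% M                                # subject scores on the effect
    d <- ncol(Z)
    mz <- colMeans(Z)
    ss_eff <- n * sum(mz^2)
    ss_err <- sum(sweep(Z, 2, mz)^2)
    df1 <- d; df2 <- d * (n - 1)
    Fval <- (ss_eff / df1) / (ss_err / df2)
    # GG epsilon from the covariance of the effect scores
    S <- stats::cov(Z)
    eps <- sum(diag(S))^2 / (d * sum(S * S))
    eps <- min(max(eps, 1 / d), 1)
    res[[nm]] <- data.frame(
      effect = nm, df1 = df1, df2 = df2, F = Fval,
      p = pf(Fval, df1, df2, lower.tail = FALSE),
      eps_gg = eps, df1_gg = eps * df1, df2_gg = eps * df2,
      p_gg = pf(Fval, eps * df1, eps * df2, lower.tail = FALSE),
      ss_effect = ss_eff, ss_error = ss_err,
      stringsAsFactors = FALSE
    )
    ss_err_all <- ss_err_all + ss_err
  }
  out <- do.call(rbind, res)
  out$eta_g_sq <- out$ss_effect / (out$ss_effect + ss_subj + ss_err_all)
  rownames(out) <- NULL
  class(out) <- c("rm_anova", class(out))
  out
}

#' Paired post hoc t-tests with Bonferroni correction
#'
#' @param data Long data frame.
#' @param dv,subject Column names for the value and subject id.
#' @param factor_col Column holding the condition labels.
#' @param comparisons List of length-2 character vectors of levels to
#'   compare; `NULL` compares all pairs.
#' @param conf_level Confidence level for the difference CI.
#' @return Data frame with `t`, `df`, `p`, `p_adj` (Bonferroni, capped at
#'   1), paired Cohen's `d` (mean difference over SD of differences) and
#'   the CI of the mean difference.
#' @export
posthoc_ttests <- function(data, dv, factor_col, subject, comparisons = NULL,
                           conf_level = 0.95) {
  stopifnot(all(c(dv, factor_col, subject) %in% names(data)))
  levs <- unique(as.character(data[[factor_col]]))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(levs, 2, simplify = FALSE)
  }
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    a <- data[data[[factor_col]] == cmp[1], c(subject, dv)]
    b <- data[data[[factor_col]] == cmp[2], c(subject, dv)]
    merged <- merge(a, b, by = subject)
    d <- merged[[paste0(dv, ".x")]] - merged[[paste0(dv, ".y")]]
    if (sd(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = length(d) - 1),
                 p.value = if (all(d == 0)) 1 else NA_real_,
                 conf.int = c(mean(d), mean(d)))
      dz <- 0
    } else {
      tt <- t.test(d, conf.level = conf_level)
      dz <- mean(d) / sd(d)
    }
    data.frame(level1 = cmp[1], level2 = cmp[2],
               mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, p_adj = min(1, tt$p.value * m),
               cohens_d = dz,
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile bootstrap confidence interval across observers
#'
#' @param values Numeric vector (one value per observer) or a matrix /
#'   data frame with observers in rows.
#' @param statistic Function reducing a resampled set of observers to a
#'   scalar (default `mean`, applied column-wise then passed through for
#'   matrices via `colMeans`).
#' @param level Confidence level (default 0.68, the conventional
#'   1-SEM-like band for psychophysics error bars).
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return For a vector: `c(lo, hi)` (plus attributes `level`, `B`).
#' @export
bootstrap_ci <- function(values, statistic = mean, level = 0.68, B = 1000L,
                         seed = 1L) {
  if (is.data.frame(values)) values <- as.matrix(values)
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (n < 1) stopf("need at least one observer")
  stat_of <- function(idx) {
    if (is.matrix(values)) statistic(values[idx, , drop = FALSE]) else statistic(values[idx])
  }
  boots <- with_seed(seed, {
    vapply(seq_len(B), function(b) stat_of(sample.int(n, n, replace = TRUE)),
           numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- if (level >= 1) range(boots) else unname(quantile(boots, c(alpha, 1 - alpha), type = 7))
  attr(ci, "level") <- level
  attr(ci, "B") <- B
  attr(ci, "point") <- stat_of(seq_len(n))
  ci
}

#' Spearman correlation between cortical surface area and CSF attributes
#'
#' Stacks matched (observer, meridian) pairs and computes the Spearman
#' rank correlation between V1 surface area and a contrast-sensitivity
#' attribute, one- or two-tailed.
#'
#' @param surface_areas Data frame with columns `observer`, `meridian`,
#'   `area_mm2`.
#' @param attributes Data frame with columns `observer`, `meridian`,
#'   `value`.
#' @param tail `"one"` (positive association expected) or `"two"`.
#' @return List with `rho`, `p`, `n_pairs`, `tail`.
#' @export
meridian_correlation <- function(surface_areas, attributes,
                                 tail = c("one", "two")) {
  tail <- match.arg(tail)
  stopifnot(all(c("observer", "meridian", "area_mm2") %in% names(surface_areas)),
            all(c("observer", "meridian", "value") %in% names(attributes)))
  merged <- merge(surface_areas, attributes, by = c("observer", "meridian"))
  if (nrow(merged) < 3) stopf("need at least 3 matched (observer, meridian) pairs")
  ct <- suppressWarnings(cor.test(merged$area_mm2, merged$value,
                                  method = "spearman",
                                  alternative = if (tail == "one") "greater" else "two.sided",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value,
       n_pairs = nrow(merged), tail = tail)
}
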