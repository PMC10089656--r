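# Shared fixtures for the csfield test suite. Everything is generated in
# code; no binary fixtures.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A single-cell design for recovery simulations: one LVM cell at 2 deg,
# best PEST, n trials per SF.
one_cell_design <- function(trials_per_sf, procedure = "pest",
                            angle = "LVM", ecc = 2) {
  experiment_design(conditions = data.frame(
    condition = "VM", angle = angle, ecc = ecc, scaled = FALSE,
    procedure = procedure, trials_per_sf = as.integer(trials_per_sf)))
}

# Fixed-size-only design (no M-scale condition) at a common per-SF count.
fixed_design <- function(trials_per_sf) {
  des <- experiment_design()
  des$conditions <- des$conditions[!des$conditions$scaled, , drop = FALSE]
  des$conditions$trials_per_sf <- as.integer(trials_per_sf)
  des
}

# Closed-form attributes of the log parabola S(f) = delta *
# exp(-(log2(f/alpha)/beta)^2), used as the independent oracle.
lp_closed_form <- function(alpha, beta, delta, f_lo = 0.25, f_hi = 24) {
  peak_sf <- alpha
  peak_cs <- delta
  cutoff <- alpha * 2^(beta * sqrt(log(delta)))   # S(cutoff) = 1
  bandwidth <- 2 * beta * sqrt(0.5 * log(delta))  # log10 half-max width
  # AULCSF: log10 S is a downward parabola in u = log10 f,
  # g(u) = A - B (u - u0)^2 with A = log10 delta, u0 = log10 alpha,
  # B = log10(e) / (beta * log10 2)^2; integrate max(g, 0) on the window.
  A <- log10(delta); u0 <- log10(alpha)
  B <- log10(exp(1)) / (beta * log10(2))^2
  r <- sqrt(A / B)
  lo <- max(log10(f_lo), u0 - r); hi <- min(log10(f_hi), u0 + r)
  aul <- if (hi <= lo) 0 else {
    F <- function(u) A * u - B * (u - u0)^3 / 3
    F(hi) - F(lo)
  }
  list(peak_sf = peak_sf, peak_cs = peak_cs, cutoff_sf = cutoff,
       bandwidth = bandwidth, aulcsf = aul)
}

# Minimal hand-built fit objects for ranking-arithmetic tests.
fake_fit <- function(bic, k, model = "LP", label = "+Ecc +HVA +VMA",
                     sig = c(n = 10, sy = 5, sc = -1, sf = 2)) {
  n <- 100
  loglik <- (k * log(n) - bic) / 2
  structure(list(csf_model = model,
                 vf_spec = list(label = label, partition = c(LVM_2 = "g")),
                 params = list(), loglik = loglik, k = k, n = n, bic = bic,
                 convergence = list(), opts = fit_opts(),
                 data_signature = sig),
            class = "csf_fit")
}
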