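#' Best-PEST adaptive procedure
#'
#' Maximum-likelihood adaptive placement: after each trial the next
#' contrast is the grid level maximising the likelihood of the response
#' history under the fixed-slope logistic CRF viewed as a function of
#' the threshold `ct` (guess and lapse fixed at `pl` and `1 - pu`).
#' Exact likelihood ties resolve to the lower contrast.
#'
#' `pest_init()` builds the state; `pest_observe()` folds in one trial
#' (incremental update of the per-candidate log-likelihoods);
#' [best_pest_next()] returns the next placement.
#'
#' @param grid Candidate log10-contrast levels (default 61 points on
#'   \[-3, 0\]).
#' @param crf A [crf_spec()].
#' @param start Initial log10 contrast before any data (default
#'   `log10(0.5)`, mid-range linear contrast).
#' @return A `"pest_state"` object.
#' @export
pest_init <- function(grid = seq(-3, 0, length.out = 61), crf = crf_spec(),
                      start = log10(0.5)) {
  if (length(grid) < 1) stopf("grid must be nonempty")
  grid <- sort(grid)
  structure(list(grid = grid, crf = crf, start = start,
                 cum_ll = numeric(length(grid)), n = 0L,
                 history = data.frame(log10_contrast = numeric(0),
                                      response = integer(0))),
            class = "pest_state")
}

#' @rdname pest_init
#' @param state A `"pest_state"`.
#' @param c Log10 contrast shown on the trial.
#' @param response 0/1 correctness.
#' @export
pest_observe <- function(state, c, response) {
  stopifnot(inherits(state, "pest_state"), response %in% c(0, 1))
  p <- crf_probability(c, state$crf, ct = state$grid)
  state$cum_ll <- state$cum_ll +
    if (response == 1) log(p) else log(1 - p)
  state$n <- state$n + 1L
  state$history <- rbind(state$history,
                         data.frame(log10_contrast = c, response = as.integer(response)))
  state
}

#' @rdname pest_init
#' @return `best_pest_next()`: the next log10-contrast placement (the
#'   current maximum-likelihood threshold estimate, clamped to the grid).
#' @export
best_pest_next <- function(state) {
  stopifnot(inherits(state, "pest_state"))
  if (state$n == 0L) return(state$start)
  state$grid[which.max(state$cum_ll)]  # first max = lowest contrast on ties
}

#' Weighted 3-down-1-up staircase
#'
#' Contrast decreases by `down_step` after three consecutive correct
#' responses and increases by `up_step` after any error; the counter
#' resets on every movement. With
#' `up_step = down_step * p^3 / (1 - p^3)` at `p = 0.75` the expected
#' drift vanishes at the 75%-correct contrast, so the staircase
#' converges at 75% rather than the classic unweighted 79.4%.
#'
#' @param start Initial log10 contrast (default `log10(0.5)`).
#' @param down_step Step down in log10 units (default 0.05).
#' @param up_step Step up; defaults to the 75%-equilibrium weighting.
#' @param bounds Log10-contrast clamp (default \[-3, 0\]; physical
#'   contrast cannot exceed 1).
#' @return A `"staircase_state"` object.
#' @export
staircase_init <- function(start = log10(0.5), down_step = 0.05,
                           up_step = down_step * 0.75^3 / (1 - 0.75^3),
                           bounds = c(-3, 0)) {
  structure(list(level = min(max(start, bounds[1]), bounds[2]),
                 counter = 0L, down_step = down_step, up_step = up_step,
                 bounds = bounds, last_direction = 0L,
                 reversals = numeric(0), n = 0L),
            class = "staircase_state")
}

#' @rdname staircase_init
#' @param state A `"staircase_state"`.
#' @param response 0/1 correctness at the current level.
#' @return `staircase_update()`: the updated state; `$level` is the next
#'   placement and `$reversals` logs levels at direction reversals.
#' @export
staircase_update <- function(state, response) {
  stopifnot(inherits(state, "staircase_state"), response %in% c(0, 1))
  state$n <- state$n + 1L
  move <- 0L
  if (response == 0) {
    move <- 1L                                  # up on any error
  } else {
    state$counter <- state$counter + 1L
    if (state$counter == 3L) move <- -1L        # down on a triple
  }
  if (move != 0L) {
    if (state$last_direction != 0L && move != state$last_direction) {
      state$reversals <- c(state$reversals, state$level)
    }
    step <- if (move > 0L) state$up_step else -state$down_step
    state$level <- min(max(state$level + step, state$bounds[1]), state$bounds[2])
    state$last_direction <- move
    state$counter <- 0L
  }
  state
}

#' Run an adaptive titration against a ground-truth observer
#'
#' Simulates one titration track for a single (cell, spatial frequency)
#' combination: each combination has its own independent adaptive state,
#' matching the experimental design. Responses are Bernoulli draws from
#' the observer's true CRF.
#'
#' @param observer A [make_observer()] ground-truth observer.
#' @param procedure `"pest"` (best PEST) or `"staircase"`.
#' @param cell Cell id (see [location_cells()]) present in the observer.
#' @param f Spatial frequency in cpd.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param grid Log10-contrast grid for placement/clamping.
#' @param start Initial log10 contrast.
#' @return A list with `trials` (data frame: `trial`, `sf`,
#'   `log10_contrast`, `response`), `estimate` (log10 threshold: whole-run
#'   ML estimate for best PEST, mean of the last six reversals for the
#'   staircase), and `true_ct`.
#' @export
run_titration <- function(observer, procedure = c("pest", "staircase"),
                          cell, f, n_trials, seed = 1L,
                          grid = seq(-3, 0, length.out = 61),
                          start = log10(0.5)) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(observer, "csf_observer"))
  if (n_trials < 1) stopf("n_trials must be >= 1")
  pars <- observer$params[[cell]]
  if (is.null(pars)) stopf("observer has no cell '%s'", cell)
  crf <- observer$crf
  true_ct <- -log10(max(csf_sensitivity(pars, f), .Machine$double.xmin))

  with_seed(seed, {
    lev <- numeric(n_trials); resp <- integer(n_trials)
    if (procedure == "pest") {
      st <- pest_init(grid = grid, crf = crf, start = start)
      for (i in seq_len(n_trials)) {
        c_i <- best_pest_next(st)
        p_i <- crf_probability(c_i, crf, ct = true_ct)
        y_i <- sample_response(p_i)
        st <- pest_observe(st, c_i, y_i)
        lev[i] <- c_i; resp[i] <- y_i
      }
      estimate <- best_pest_next(st)
    } else {
      st <- staircase_init(start = start, bounds = range(grid))
      for (i in seq_len(n_trials)) {
        c_i <- st$level
        p_i <- crf_probability(c_i, crf, ct = true_ct)
        y_i <- sample_response(p_i)
        st <- staircase_update(st, y_i)
        lev[i] <- c_i; resp[i] <- y_i
      }
      rev <- st$reversals
      estimate <- if (length(rev) >= 1) {
        mean(rev[max(1, length(rev) - 5):length(rev)])
      } else {
        mean(lev[max(1, n_trials - 9):n_trials])   # degenerate short run
      }
    }
    list(trials = data.frame(trial = seq_len(n_trials), sf = f,
                             log10_contrast = lev, response = resp),
         estimate = estimate, true_ct = true_ct)
  })
}
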