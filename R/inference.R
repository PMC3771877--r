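#' Fit the relative fecundity from an observed frequency change
#'
#' Solves for the fecundity `F` such that `n_gens` generations of the no-CI
#' recursion [step_no_ci()] carry the infection frequency from `p0` to `p1`,
#' given the transmission leakage `mu`. The final frequency is monotone
#' increasing in `F` for fixed `p0`, `mu` and `n_gens`, so a bisection on
#' `F` is used.
#'
#' @param p0,p1 Initial and final infection frequencies, both in (0, 1).
#' @param n_gens Number of generations separating the two observations.
#' @param mu Transmission leakage of the strain.
#' @param bracket Initial search interval for `F`; expanded (up to 2^10
#'   fold) if it does not bracket the target.
#' @param tol Convergence tolerance on the final frequency.
#' @return A list with `F` (the fitted fecundity), `residual` (final
#'   frequency at `F` minus `p1`) and `bracket` (the interval searched).
#' @examples
#' fit_F(p0 = 0.054, p1 = 0.529, n_gens = 120, mu = 0.023)$F  # about 1.061
#' @export
fit_F <- function(p0, p1, n_gens, mu, bracket = c(0.5, 2), tol = 1e-8) {
  p0 <- check_freq(p0, "p0"); p1 <- check_freq(p1, "p1")
  if (p0 <= 0 || p0 >= 1 || p1 <= 0 || p1 >= 1)
    stop("'p0' and 'p1' must lie strictly inside (0, 1)", call. = FALSE)
  n_gens <- as.integer(n_gens)
  if (is.na(n_gens) || n_gens < 1L) stop("'n_gens' must be >= 1", call. = FALSE)
  mu <- check_freq(mu, "mu")
  # ceiling: even as F -> Inf, one step maps p to at most (1 - mu), so the
  # reachable final frequency is bounded; detect unattainable targets early
  final_at <- function(Fv) {
    traj <- iterate_strain(p0, strain_params(F = Fv, mu = mu), n_gens)
    traj$p[n_gens + 1L]
  }
  lo <- bracket[1]; hi <- bracket[2]
  for (k in 1:10) {
    if (final_at(hi) >= p1) break
    hi <- hi * 2
  }
  if (final_at(hi) < p1)
    stop(sprintf(paste0("target frequency %.4g unattainable in %d generations ",
                        "for any F <= %.3g (mu-limited ceiling)"),
                 p1, n_gens, hi), call. = FALSE)
  for (k in 1:10) {
    if (final_at(lo) <= p1) break
    lo <- lo / 2
  }
  if (final_at(lo) > p1)
    stop("target frequency below reach of any F in the expanded bracket",
         call. = FALSE)
  root <- stats::uniroot(function(Fv) final_at(Fv) - p1,
                         lower = lo, upper = hi, tol = 1e-12)
  Fhat <- root$root
  res <- final_at(Fhat) - p1
  if (abs(res) > tol)
    stop(sprintf("bisection did not converge: residual %.3g", res), call. = FALSE)
  list(F = Fhat, residual = res, bracket = c(lo, hi))
}

#' Trajectory grid across candidate parameter combinations
#'
#' Runs the no-CI recursion from `p0` for each `(F, mu)` combination and
#' flags a combination as "sufficient" to explain an observed final
#' frequency when its predicted final frequency is at least the lower
#' confidence bound of the observation. The observed point estimate itself
#' need not be reached: sampling error in the observation is acknowledged
#' through its interval.
#'
#' @param p0 Initial frequency shared by all combinations.
#' @param n_gens Number of generations.
#' @param combos A list of [strain_params()] objects.
#' @param observed Observed final frequency (optional; used in the output
#'   only).
#' @param ci_lower Lower confidence bound of the observed final frequency;
#'   the sufficiency threshold.
#' @return A list with `trajectories` (list of data frames from
#'   [iterate_strain()]) and `summary` (data frame with one row per combo:
#'   `F`, `mu`, `p_final`, `sufficient`).
#' @examples
#' combos <- list(strain_params(1.061, 0.023),
#'                strain_params(1.11, 0.04),
#'                strain_params(1.026, 0.01))
#' trajectory_grid(0.054, 120, combos, observed = 0.565,
#'                 ci_lower = 0.458)$summary
#' @export
trajectory_grid <- function(p0, n_gens, combos, observed = NA_real_,
                            ci_lower = NA_real_) {
  if (!length(combos)) stop("'combos' must be non-empty", call. = FALSE)
  stopifnot(all(vapply(combos, inherits, logical(1), "wb_strain_params")))
  trajs <- lapply(combos, function(pr) iterate_strain(p0, pr, n_gens))
  pf <- vapply(trajs, function(tr) tr$p[nrow(tr)], numeric(1))
  summ <- data.frame(
    F = vapply(combos, `[[`, numeric(1), "F"),
    mu = vapply(combos, `[[`, numeric(1), "mu"),
    p_final = pf,
    sufficient = if (is.na(ci_lower)) NA else pf >= ci_lower)
  list(trajectories = trajs, summary = summ,
       observed = observed, ci_lower = ci_lower)
}

#' Minimal CI-strain fecundity needed to displace the resident strain
#'
#' Finds, by bisection, the smallest `F_R` such that the frequency of the
#' resident non-CI strain A falls below `threshold` within `horizon`
#' generations of the two-strain recursion, holding all other parameters
#' fixed. Displacement speed is monotone in `F_R`, which makes the
#' criterion a threshold in `F_R`.
#'
#' @param start Initial [pop_state()].
#' @param params A [two_strain_params()] object; its `F_R` entry is
#'   ignored (it is the unknown).
#' @param threshold Displacement criterion: strain A must fall below this
#'   frequency.
#' @param horizon Number of generations allowed.
#' @param bracket Search interval for `F_R`.
#' @param tol Bisection tolerance on `F_R`.
#' @return The minimal `F_R` (scalar).
#' @examples
#' pars <- two_strain_params(1.061, 0.023, F_R = 1, mu_R = 0.045, H = 0.55)
#' required_FR(pop_state(0.54, 0.09), pars, threshold = 0.01, horizon = 40)
#' @export
required_FR <- function(start, params, threshold, horizon,
                        bracket = c(0.5, 2), tol = 1e-4) {
  stopifnot(inherits(start, "wb_pop_state"),
            inherits(params, "wb_two_strain_params"))
  threshold <- check_freq(threshold, "threshold")
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]", call. = FALSE)
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) stop("'horizon' must be >= 1", call. = FALSE)
  displaced <- function(FR) {
    pr <- two_strain_params(params$F_A, params$mu_A, FR, params$mu_R, params$H)
    traj <- iterate_two_strain(start, pr, horizon)
    any(traj$p_A[-1L] < threshold)
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (displaced(lo)) return(lo)
  if (!displaced(hi))
    stop(sprintf("displacement below %.3g within %d generations unattainable for F_R in [%g, %g]",
                 threshold, horizon, lo, hi), call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (displaced(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Convert years to host generations
#'
#' Drosophila simulans populations turn over many generations per year; the
#' conversion factor depends on climate (roughly 20 generations per year in
#' subtropical coastal populations, 15 in temperate ones).
#'
#' @param years Elapsed time in years (>= 0).
#' @param generations_per_year Positive conversion factor.
#' @return Nearest integer number of generations.
#' @examples
#' years_to_generations(6, 20)   # 120
#' years_to_generations(3, 15)   # 45
#' @export
years_to_generations <- function(years, generations_per_year) {
  stopifnot(is.numeric(years), years >= 0,
            is.numeric(generations_per_year), generations_per_year > 0)
  as.integer(round(years * generations_per_year))
}
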