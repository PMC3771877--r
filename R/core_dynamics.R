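#' One generation of a non-CI strain
#'
#' Discrete-generation recursion for a single maternally inherited strain
#' that causes no cytoplasmic incompatibility. With relative fecundity `F`
#' and transmission leakage `mu`,
#' \deqn{p' = \frac{F(1-\mu)p}{1 + (F-1)p}.}
#' The denominator is the mean fecundity; infected mothers contribute a
#' fraction `1 - mu` of infected ova.
#'
#' @param p Frequency of infected adults (may be a vector).
#' @param params A [strain_params()] object; `H` is ignored (no CI).
#' @return Next-generation infection frequency, same length as `p`.
#' @examples
#' au <- strain_params(F = 1.061, mu = 0.023)
#' step_no_ci(0.054, au)
#' @seealso [step_ci()], [equilibrium_no_ci()]
#' @export
step_no_ci <- function(p, params) {
  stopifnot(inherits(params, "wb_strain_params"))
  p <- check_freq(p)
  params$F * (1 - params$mu) * p / (1 + (params$F - 1) * p)
}

#' One generation of a CI-inducing strain
#'
#' Single-strain recursion with cytoplasmic incompatibility: sperm from
#' infected males (frequency `p`) reduces the hatch of uninfected ova by the
#' factor `1 - s_h * p`, where `s_h = 1 - H` is the CI strength. Infected
#' ova are compatible with all sperm:
#' \deqn{p' = \frac{F(1-\mu)p}{F(1-\mu)p + [(1-p) + F\mu p](1 - s_h p)}.}
#' With `H = 1` this reduces exactly to [step_no_ci()].
#'
#' @inheritParams step_no_ci
#' @param params A [strain_params()] object (its `H` matters here).
#' @return Next-generation infection frequency.
#' @examples
#' ri <- strain_params(F = 1.08, mu = 0.045, H = 0.55)
#' step_ci(0.3, ri)
#' @export
step_ci <- function(p, params) {
  stopifnot(inherits(params, "wb_strain_params"))
  p <- check_freq(p)
  num <- params$F * (1 - params$mu) * p
  den <- num + ((1 - p) + params$F * params$mu * p) * (1 - params$s_h * p)
  if (any(den <= 0)) stop("mean fitness is zero: degenerate parameters", call. = FALSE)
  num / den
}

#' Equilibrium analysis for a non-CI strain
#'
#' A non-CI strain persists only if the fecundity benefit offsets the
#' transmission leakage, `F(1 - mu) > 1`. It then increases from any
#' positive frequency (Fisherian dynamics, unstable equilibrium at 0) to
#' the stable equilibrium
#' \deqn{p_s = 1 - \frac{F\mu}{F-1},}
#' the haploid mutation-selection balance with the uninfected class in the
#' role of the deleterious mutant. Otherwise the infection is lost
#' (`no_invasion`).
#'
#' @param params A [strain_params()] object.
#' @return An object of class `wb_equilibrium` with fields `p_u`, `p_s`
#'   (`NA` when absent) and `regime` (`"fisherian"`, `"bistable"` or
#'   `"no_invasion"`).
#' @examples
#' equilibrium_no_ci(strain_params(F = 1.061, mu = 0.023))
#' @export
equilibrium_no_ci <- function(params) {
  stopifnot(inherits(params, "wb_strain_params"))
  if (params$F * (1 - params$mu) > 1) {
    ps <- 1 - params$F * params$mu / (params$F - 1)
    equilibrium_result("fisherian", p_u = 0, p_s = ps)
  } else {
    equilibrium_result("no_invasion", p_u = 0, p_s = NA_real_)
  }
}

#' Equilibria of the single-strain CI model
#'
#' Interior fixed points of [step_ci()] are the roots in (0, 1) of
#' \deqn{s_h(1 - F\mu)p^2 + [F(1-\mu) + F\mu - 1 - s_h]p + [1 - F(1-\mu)] = 0.}
#' When `F(1 - mu) > 1` the infection spreads from any positive frequency:
#' the unstable equilibrium is 0 and the single interior root is the stable
#' equilibrium (regime `"fisherian"`). When `H < F(1 - mu) < 1` there are
#' two interior roots: the smaller is the invasion threshold `p_u`, the
#' larger the stable equilibrium `p_s` (regime `"bistable"`). With no
#' interior root and `F(1 - mu) < 1` the infection cannot persist
#' (`"no_invasion"`).
#'
#' @param params A [strain_params()] object with `H < 1`; with `H = 1` the
#'   computation delegates to [equilibrium_no_ci()].
#' @return A `wb_equilibrium` object (see [equilibrium_no_ci()]).
#' @examples
#' # strong CI can maintain a costly infection above a threshold frequency
#' equilibria_ci(strain_params(F = 0.95, mu = 0.045, H = 0.55))
#' # a fitness benefit removes the threshold entirely
#' equilibria_ci(strain_params(F = 1.1, mu = 0.045, H = 0.55))
#' @export
equilibria_ci <- function(params) {
  stopifnot(inherits(params, "wb_strain_params"))
  if (params$s_h == 0) return(equilibrium_no_ci(params))
  Fv <- params$F; mu <- params$mu; sh <- params$s_h
  a <- sh * (1 - Fv * mu)
  b <- Fv * (1 - mu) + Fv * mu - 1 - sh
  cc <- 1 - Fv * (1 - mu)
  roots <- solve_quadratic(a, b, cc)
  tol <- 1e-12
  interior <- roots[roots > tol & roots < 1 - tol]
  fisherian <- Fv * (1 - mu) >= 1
  if (fisherian) {
    ps <- if (length(interior)) max(interior) else if (mu == 0) 1 else NA_real_
    if (is.na(ps)) stop("no stable equilibrium found despite F(1-mu) >= 1",
                        call. = FALSE)
    equilibrium_result("fisherian", p_u = 0, p_s = ps)
  } else if (length(interior) >= 2L) {
    equilibrium_result("bistable", p_u = min(interior), p_s = max(interior))
  } else {
    equilibrium_result("no_invasion", p_u = 0, p_s = NA_real_)
  }
}

# real roots of a x^2 + b x + c = 0, degenerate cases handled as linear
solve_quadratic <- function(a, b, cc) {
  if (abs(a) < .Machine$double.eps) {
    if (abs(b) < .Machine$double.eps) return(numeric(0))
    return(-cc / b)
  }
  disc <- b * b - 4 * a * cc
  if (disc < 0) return(numeric(0))
  # numerically stable form: avoid cancellation in -b +/- sqrt(disc)
  q <- -(b + sign(b + (b == 0)) * sqrt(disc)) / 2
  r <- c(q / a, if (q != 0) cc / q else -b / a - q / a)
  sort(unique(r))
}

equilibrium_result <- function(regime, p_u, p_s) {
  regime <- match.arg(regime, c("fisherian", "bistable", "no_invasion"))
  if (regime == "fisherian" && (p_u != 0 || is.na(p_s)))
    stop("fisherian regime requires p_u = 0 and a stable equilibrium")
  if (regime == "bistable" && !(p_u > 0 && p_u < p_s && p_s < 1))
    stop("bistable regime requires 0 < p_u < p_s < 1")
  if (regime == "no_invasion" && !is.na(p_s))
    stop("no_invasion regime has no stable equilibrium")
  structure(list(p_u = p_u, p_s = p_s, regime = regime),
            class = "wb_equilibrium")
}

#' @export
print.wb_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium analysis (%s): p_u = %s, p_s = %s\n", x$regime,
              format(x$p_u), if (is.na(x$p_s)) "absent" else format(x$p_s)))
  invisible(x)
}

#' Invert the no-CI equilibrium for the relative fecundity
#'
#' Given an observed stable infection frequency `p_hat` of a non-CI strain
#' and its transmission leakage `mu`, solve the equilibrium condition of
#' [equilibrium_no_ci()] exactly for the relative fecundity:
#' \deqn{F = \frac{1-\hat p}{(1-\hat p) - \mu}.}
#'
#' @param p_hat Observed equilibrium frequency, in (0, 1).
#' @param mu Transmission leakage; must satisfy `mu < 1 - p_hat`, otherwise
#'   no finite fecundity can sustain the equilibrium.
#' @return The relative fecundity `F` (a scalar > 1 when `mu > 0`).
#' @examples
#' invert_equilibrium_F(0.6, 0.023)  # about 1.061
#' @export
invert_equilibrium_F <- function(p_hat, mu) {
  p_hat <- check_freq(p_hat, "p_hat")
  mu <- check_freq(mu, "mu")
  if (p_hat <= 0 || p_hat >= 1)
    stop("'p_hat' must lie strictly inside (0, 1)", call. = FALSE)
  if (mu >= 1 - p_hat)
    stop("no finite fecundity sustains this equilibrium: mu >= 1 - p_hat",
         call. = FALSE)
  (1 - p_hat) / ((1 - p_hat) - mu)
}

#' One generation of the two-strain model
#'
#' Joint recursion for the three cytoplasm classes: uninfected (O),
#' infected with the non-CI strain A, and infected with the CI strain R.
#' The unnormalized next-generation weights are each a product of an ova
#' term and a hatch term; R-infected males (frequency `p_R`) reduce the
#' hatch of O and A ova by the factor `1 - s_h * p_R`, while R ova are
#' compatible with all sperm:
#' \deqn{w_O = [p_O + F_A \mu_A p_A + F_R \mu_R p_R](1 - s_h p_R)}
#' \deqn{w_A = [F_A (1-\mu_A) p_A](1 - s_h p_R)}
#' \deqn{w_R = F_R (1-\mu_R) p_R}
#' and the next state is the weights divided by their sum (the mean
#' fitness). With `p_R = 0` the A dynamics reduce to [step_no_ci()]; with
#' `p_A = 0` the R dynamics reduce to [step_ci()].
#'
#' @param state A [pop_state()] object.
#' @param params A [two_strain_params()] object.
#' @return A [pop_state()] with the next-generation frequencies.
#' @examples
#' pars <- two_strain_params(1.061, 0.023, 1.08, 0.045, 0.55)
#' step_two_strain(pop_state(0.54, 0.09), pars)
#' @export
step_two_strain <- function(state, params) {
  stopifnot(inherits(state, "wb_pop_state"),
            inherits(params, "wb_two_strain_params"))
  w <- two_strain_weights(state[["p_A"]], state[["p_R"]], state[["p_O"]], params)
  wbar <- sum(w)
  if (wbar <= 0) stop("mean fitness is zero: population has no viable offspring",
                      call. = FALSE)
  pop_state(p_A = w[["A"]] / wbar, p_R = w[["R"]] / wbar, p_O = w[["O"]] / wbar)
}

# unnormalized class weights shared by step_two_strain and step_cyto
two_strain_weights <- function(p_A, p_R, p_O, params) {
  hatch <- 1 - params$s_h * p_R
  c(O = (p_O + params$F_A * params$mu_A * p_A + params$F_R * params$mu_R * p_R) * hatch,
    A = params$F_A * (1 - params$mu_A) * p_A * hatch,
    R = params$F_R * (1 - params$mu_R) * p_R)
}

#' Iterate the two-strain recursion
#'
#' @param state0 Initial [pop_state()].
#' @param params A [two_strain_params()] object.
#' @param n_gens Number of generations (>= 0).
#' @return A data frame of class `wb_trajectory` with columns `generation`
#'   (0 to `n_gens`), `p_A`, `p_R`, `p_O`; row 1 is `state0`.
#' @examples
#' pars <- two_strain_params(1.061, 0.023, 1.08, 0.045, 0.55)
#' traj <- iterate_two_strain(pop_state(0.54, 0.09), pars, 45)
#' tail(traj, 1)
#' @export
iterate_two_strain <- function(state0, params, n_gens) {
  stopifnot(inherits(state0, "wb_pop_state"),
            inherits(params, "wb_two_strain_params"))
  n_gens <- as.integer(n_gens)
  if (is.na(n_gens) || n_gens < 0L) stop("'n_gens' must be >= 0", call. = FALSE)
  out <- matrix(NA_real_, nrow = n_gens + 1L, ncol = 3L,
                dimnames = list(NULL, c("p_A", "p_R", "p_O")))
  s <- state0
  out[1L, ] <- unclass(s)
  if (n_gens > 0L) for (t in seq_len(n_gens)) {
    s <- step_two_strain(s, params)
    out[t + 1L, ] <- unclass(s)
  }
  structure(data.frame(generation = 0:n_gens, out),
            class = c("wb_trajectory", "data.frame"))
}

#' Iterate a single-strain recursion
#'
#' Convenience wrapper applying [step_ci()] (or [step_no_ci()] when
#' `params$H == 1`; the two coincide in that case) for `n_gens` generations.
#'
#' @param p0 Initial infection frequency.
#' @param params A [strain_params()] object.
#' @param n_gens Number of generations (>= 0).
#' @return A data frame with columns `generation` and `p`.
#' @examples
#' iterate_strain(0.054, strain_params(1.061, 0.023), 120)[121:121, ]
#' @export
iterate_strain <- function(p0, params, n_gens) {
  stopifnot(inherits(params, "wb_strain_params"))
  p0 <- check_freq(p0, "p0")
  n_gens <- as.integer(n_gens)
  if (is.na(n_gens) || n_gens < 0L) stop("'n_gens' must be >= 0", call. = FALSE)
  p <- numeric(n_gens + 1L)
  p[1L] <- p0
  if (n_gens > 0L) for (t in seq_len(n_gens)) p[t + 1L] <- step_ci(p[t], params)
  data.frame(generation = 0:n_gens, p = p)
}

#' Can a strain increase when very rare?
#'
#' Rare-invasion conditions of the two-strain model. An invader entering an
#' uninfected population increases iff `F(1 - mu) > 1` (CI is irrelevant at
#' low frequency because infected males are rare). Strain R entering a
#' population where strain A sits at its stable equilibrium increases iff
#' `F_R(1 - mu_R) > F_A(1 - mu_A)`.
#'
#' Note that failure of the rare-invasion condition does not preclude
#' displacement of A by R from a non-negligible starting frequency, where
#' CI already operates; compare with trajectories from
#' [iterate_two_strain()].
#'
#' @param params A [two_strain_params()] object.
#' @param invader `"A"` or `"R"`.
#' @param resident `"none"` (uninfected population) or `"A"` (strain A at
#'   its stable equilibrium; only valid with `invader = "R"`).
#' @return `TRUE` if the invader strictly increases when rare.
#' @examples
#' pars <- two_strain_params(1.061, 0.023, 1.08, 0.045, 0.55)
#' invades_when_rare(pars, "A")                   # wAu into uninfected
#' invades_when_rare(pars, "R", resident = "A")   # condition (2)-style check
#' @export
invades_when_rare <- function(params, invader = c("A", "R"),
                              resident = c("none", "A")) {
  stopifnot(inherits(params, "wb_two_strain_params"))
  invader <- match.arg(invader)
  resident <- match.arg(resident)
  if (resident == "none") {
    if (invader == "A") params$F_A * (1 - params$mu_A) > 1
    else params$F_R * (1 - params$mu_R) > 1
  } else {
    if (invader != "R")
      stop("with resident 'A' only invader 'R' is supported", call. = FALSE)
    if (params$F_A * (1 - params$mu_A) <= 1)
      stop("resident strain A does not persist on its own (F_A(1-mu_A) <= 1)",
           call. = FALSE)
    params$F_R * (1 - params$mu_R) > params$F_A * (1 - params$mu_A)
  }
}

#' Write a trajectory to CSV
#'
#' Writes `generation,p_A,p_R,p_O` at full double precision.
#'
#' @param traj A trajectory from [iterate_two_strain()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
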