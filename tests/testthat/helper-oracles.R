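# Independent oracles used across test files. These deliberately avoid the
# closed forms used in R/: the step oracle enumerates mating/ova/hatch
# outcomes, the equilibrium oracle scans for fixed points on a fine grid.

# one generation of the single-strain CI model by explicit enumeration of
# (mother class, ovum type, father class) cells
oracle_step_ci <- function(p, F, mu, H) {
  classes <- c(inf = p, uninf = 1 - p)
  inf_ova <- 0
  uninf_ova <- 0
  for (mother in names(classes)) {
    fec <- if (mother == "inf") F else 1
    ova <- classes[[mother]] * fec
    if (mother == "inf") {
      inf_ova <- inf_ova + ova * (1 - mu)
      uninf_ova <- uninf_ova + ova * mu
    } else {
      uninf_ova <- uninf_ova + ova
    }
  }
  hatched_inf <- 0
  hatched_uninf <- 0
  for (father in names(classes)) {
    frac <- classes[[father]]
    # infected ova compatible with all sperm
    hatched_inf <- hatched_inf + inf_ova * frac
    # uninfected ova suffer CI from infected fathers
    hatch <- if (father == "inf") H else 1
    hatched_uninf <- hatched_uninf + uninf_ova * frac * hatch
  }
  hatched_inf / (hatched_inf + hatched_uninf)
}

# all fixed points of a scalar map on (0,1): sign-change scan + bisection
oracle_fixed_points <- function(step_fun, grid_step = 1e-5, tol = 1e-12) {
  g <- seq(grid_step, 1 - grid_step, by = grid_step)
  d <- step_fun(g) - g
  s <- sign(d)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(i) {
    lo <- g[i]; hi <- g[i + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(step_fun(mid) - mid) == sign(step_fun(lo) - lo)) lo <- mid
      else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  exact <- g[d == 0]
  sort(c(roots, exact))
}

# numerical slope of the recursion at a point (stability: |slope| < 1)
recursion_slope <- function(step_fun, p, h = 1e-7) {
  (step_fun(min(p + h, 1)) - step_fun(max(p - h, 0))) /
    (min(p + h, 1) - max(p - h, 0))
}

# Clopper-Pearson endpoints by root-solving the binomial tail equations
oracle_cp_interval <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (x == 0) 0 else
    uniroot(function(p) 1 - pbinom(x - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    uniroot(function(p) pbinom(x, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# shared fixture parameters (the two strains of the eastern-Australia system)
pars_au <- function() strain_params(F = 1.061, mu = 0.023, H = 1)
pars_ri <- function() strain_params(F = 1.08, mu = 0.045, H = 0.55)
pars_two <- function(F_R = 1.08)
  two_strain_params(1.061, 0.023, F_R, 0.045, 0.55)

random_pop_state <- function() {
  x <- runif(3)
  x <- x / sum(x)
  pop_state(x[1], x[2], x[3])
}
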