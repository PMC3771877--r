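#' Parameters for a single Wolbachia strain
#'
#' Bundles the three quantities that govern the discrete-generation dynamics
#' of one maternally inherited Wolbachia variant in a randomly mating host
#' population: the relative fecundity of infected females, the maternal
#' transmission leakage, and the relative hatch rate of incompatible
#' fertilizations.
#'
#' @param F Relative fecundity of infected females (uninfected females have
#'   fecundity 1). Must be positive. Values above 1 mean the infection is
#'   beneficial.
#' @param mu Fraction of uninfected ova produced by an infected mother
#'   (transmission leakage), in `[0, 1]`. `1 - mu` is the maternal
#'   transmission fidelity.
#' @param H Relative hatch rate of embryos from incompatible fertilizations
#'   (sperm from an infected male fertilizing ova that lack the strain), in
#'   `[0, 1]`. `H = 1` encodes a strain that causes no cytoplasmic
#'   incompatibility (CI); the CI strength is `s_h = 1 - H`.
#'
#' @return An object of class `wb_strain_params`: a list with elements
#'   `F`, `mu`, `H` and the derived `s_h = 1 - H`.
#' @examples
#' # wAu-like: no CI, mild fitness benefit, 2.3% leakage
#' strain_params(F = 1.061, mu = 0.023, H = 1)
#' # wRi-like: strong CI
#' strain_params(F = 1.08, mu = 0.045, H = 0.55)
#' @export
strain_params <- function(F, mu, H = 1) {
  stopifnot(is.numeric(F), length(F) == 1L, is.finite(F),
            is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(H), length(H) == 1L, is.finite(H))
  if (F <= 0) stop("'F' must be > 0", call. = FALSE)
  if (mu < 0 || mu > 1) stop("'mu' must lie in [0, 1]", call. = FALSE)
  if (H < 0 || H > 1) stop("'H' must lie in [0, 1]", call. = FALSE)
  structure(list(F = as.numeric(F), mu = as.numeric(mu), H = as.numeric(H),
                 s_h = 1 - as.numeric(H)),
            class = "wb_strain_params")
}

#' @export
print.wb_strain_params <- function(x, ...) {
  cat(sprintf("Wolbachia strain parameters: F = %g, mu = %g, H = %g (s_h = %g)\n",
              x$F, x$mu, x$H, x$s_h))
  invisible(x)
}

#' Parameters for the two-strain (wAu / wRi) model
#'
#' Parameters for the joint dynamics of a non-CI variant ("A", wAu-like) and
#' a CI-inducing variant ("R", wRi-like) in one host population. Strain A
#' never causes CI; strain R reduces the hatch of both uninfected and
#' A-infected ova by the common factor `H`, while R-infected ova are
#' compatible with all sperm.
#'
#' @param F_A,mu_A Relative fecundity and transmission leakage of strain A.
#' @param F_R,mu_R Relative fecundity and transmission leakage of strain R.
#' @param H Relative hatch rate of incompatible fertilizations caused by
#'   R-infected males, in `[0, 1]`.
#'
#' @return An object of class `wb_two_strain_params`.
#' @examples
#' two_strain_params(F_A = 1.061, mu_A = 0.023,
#'                   F_R = 1.08, mu_R = 0.045, H = 0.55)
#' @export
two_strain_params <- function(F_A, mu_A, F_R, mu_R, H) {
  A <- strain_params(F_A, mu_A, H = 1)
  R <- strain_params(F_R, mu_R, H = H)
  structure(list(F_A = A$F, mu_A = A$mu, F_R = R$F, mu_R = R$mu,
                 H = R$H, s_h = R$s_h),
            class = "wb_two_strain_params")
}

#' @export
print.wb_two_strain_params <- function(x, ...) {
  cat(sprintf(paste0("Two-strain parameters:\n",
                     "  A (no CI): F_A = %g, mu_A = %g\n",
                     "  R (CI):    F_R = %g, mu_R = %g, H = %g (s_h = %g)\n"),
              x$F_A, x$mu_A, x$F_R, x$mu_R, x$H, x$s_h))
  invisible(x)
}

#' Population state: frequencies of the three cytoplasm classes
#'
#' @param p_A Frequency of A-infected (wAu-like) adults.
#' @param p_R Frequency of R-infected (wRi-like) adults.
#' @param p_O Frequency of uninfected adults; defaults to `1 - p_A - p_R`.
#'
#' @return A classed numeric vector with names `p_A`, `p_R`, `p_O` summing
#'   to 1 (renormalized; the input must sum to 1 within `1e-8`).
#' @examples
#' pop_state(p_A = 0.54, p_R = 0.09)
#' @export
pop_state <- function(p_A, p_R, p_O = 1 - p_A - p_R) {
  v <- c(p_A = as.numeric(p_A), p_R = as.numeric(p_R), p_O = as.numeric(p_O))
  if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12))
    stop("state frequencies must lie in [0, 1]", call. = FALSE)
  if (abs(sum(v) - 1) > 1e-8)
    stop("state frequencies must sum to 1", call. = FALSE)
  v <- pmin(pmax(v, 0), 1)
  v <- v / sum(v)
  structure(v, class = "wb_pop_state")
}

#' @export
print.wb_pop_state <- function(x, ...) {
  cat(sprintf("Population state: p_A = %.6g, p_R = %.6g, p_O = %.6g\n",
              x[["p_A"]], x[["p_R"]], x[["p_O"]]))
  invisible(x)
}

# internal: validate scalar frequency
check_freq <- function(p, name = "p") {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("'%s' must be a frequency in [0, 1]", name), call. = FALSE)
  as.numeric(p)
}
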