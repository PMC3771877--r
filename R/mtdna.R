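#' Joint cytoplasm state: infection classes plus mtDNA haplotypes
#'
#' Because Wolbachia and mitochondria are co-transmitted through the egg,
#' each infected class carries a fixed mtDNA haplotype (strain A with
#' haplotype `"A"`, strain R with haplotype `"R"`), while the uninfected
#' class is a mixture of haplotypes: descendants of uninfected lineages
#' (ancestral haplotypes) plus uninfected "leakage" offspring of infected
#' mothers, which inherit the maternal haplotype despite losing the
#' infection.
#'
#' @param p_A,p_R Frequencies of the two infected classes.
#' @param u Named numeric vector partitioning the uninfected class by
#'   haplotype. Must contain entries `"A"` and `"R"`; any further names
#'   (default `"anc"`) are ancestral/other haplotypes. Must sum to
#'   `1 - p_A - p_R`.
#' @return An object of class `wb_cyto_state`.
#' @examples
#' # all uninfecteds ancestral, wRi already at 9%
#' cyto_state(p_A = 0, p_R = 0.09, u = c(A = 0, R = 0, anc = 0.91))
#' @export
cyto_state <- function(p_A, p_R, u) {
  p_A <- check_freq(p_A, "p_A"); p_R <- check_freq(p_R, "p_R")
  if (is.null(names(u)) || anyNA(names(u)) || any(names(u) == ""))
    stop("'u' must be a fully named vector", call. = FALSE)
  if (!all(c("A", "R") %in% names(u)))
    stop("'u' must contain entries named 'A' and 'R'", call. = FALSE)
  if (any(u < -1e-12)) stop("'u' entries must be >= 0", call. = FALSE)
  u <- pmax(u, 0)
  if (abs(p_A + p_R + sum(u) - 1) > 1e-8)
    stop("p_A + p_R + sum(u) must equal 1", call. = FALSE)
  tot <- p_A + p_R + sum(u)
  structure(list(p_A = p_A / tot, p_R = p_R / tot, u = u / tot),
            class = "wb_cyto_state")
}

#' @export
print.wb_cyto_state <- function(x, ...) {
  cat(sprintf("Cytoplasm state: p_A = %.6g, p_R = %.6g, p_O = %.6g\n",
              x$p_A, x$p_R, sum(x$u)))
  cat("  uninfected haplotypes:",
      paste(sprintf("%s = %.6g", names(x$u), x$u), collapse = ", "), "\n")
  invisible(x)
}

#' One generation of the joint infection / haplotype dynamics
#'
#' Applies the same class weights as [step_two_strain()] but decomposes the
#' uninfected-ova weight by maternal origin: uninfected mothers pass their
#' own haplotype, while leakage offspring of A- and R-infected mothers
#' enter the uninfected class carrying haplotypes `"A"` and `"R"`
#' respectively. All uninfected and A-infected ova share the CI hatch
#' factor `1 - s_h * p_R`. Marginal class frequencies are identical to
#' [step_two_strain()].
#'
#' An optional paternal mtDNA leakage rate is provided for sensitivity
#' analysis: a fraction `paternal_leak` of uninfected offspring inherit a
#' haplotype drawn from the population haplotype pool (via sperm) instead
#' of the maternal one. Paternal transmission of the infection itself is
#' never modelled. The default 0 reflects the perfect
#' infection-haplotype association expected under strictly maternal
#' co-transmission.
#'
#' @param state A [cyto_state()] object.
#' @param params A [two_strain_params()] object.
#' @param paternal_leak Probability that an uninfected offspring carries
#'   the paternal haplotype; default 0.
#' @return The next-generation [cyto_state()].
#' @examples
#' pars <- two_strain_params(1.061, 0.023, 1.08, 0.045, 0.55)
#' s <- cyto_state(0, 0.09, c(A = 0, R = 0, anc = 0.91))
#' step_cyto(s, pars)
#' @export
step_cyto <- function(state, params, paternal_leak = 0) {
  stopifnot(inherits(state, "wb_cyto_state"),
            inherits(params, "wb_two_strain_params"))
  paternal_leak <- check_freq(paternal_leak, "paternal_leak")
  p_O <- sum(state$u)
  hatch <- 1 - params$s_h * state$p_R
  # uninfected-ova weight split by maternal haplotype
  u_w <- state$u * hatch
  u_w[["A"]] <- u_w[["A"]] + params$F_A * params$mu_A * state$p_A * hatch
  u_w[["R"]] <- u_w[["R"]] + params$F_R * params$mu_R * state$p_R * hatch
  w_A <- params$F_A * (1 - params$mu_A) * state$p_A * hatch
  w_R <- params$F_R * (1 - params$mu_R) * state$p_R
  wbar <- sum(u_w) + w_A + w_R
  if (wbar <= 0) stop("mean fitness is zero", call. = FALSE)
  u_next <- u_w / wbar
  if (paternal_leak > 0 && sum(u_next) > 0) {
    pop_hap <- haplotype_pool(state)
    u_next <- (1 - paternal_leak) * u_next +
      paternal_leak * sum(u_next) * pop_hap[names(u_next)]
  }
  cyto_state(p_A = w_A / wbar, p_R = w_R / wbar, u = u_next)
}

# population haplotype frequencies (infected classes carry fixed haplotypes)
haplotype_pool <- function(state) {
  hap <- state$u
  hap[["A"]] <- hap[["A"]] + state$p_A
  hap[["R"]] <- hap[["R"]] + state$p_R
  hap
}

#' Haplotype frequency summary
#'
#' @param state A [cyto_state()] object.
#' @return A list with `population` (haplotype frequencies in the whole
#'   population, counting infected classes under their fixed haplotypes)
#'   and `within_uninfected` (haplotype composition of the uninfected
#'   class, or `NULL` when there are no uninfected individuals).
#' @examples
#' s <- cyto_state(0.5, 0, c(A = 0, R = 0.5, anc = 0))
#' haplotype_summary(s)$population
#' @export
haplotype_summary <- function(state) {
  stopifnot(inherits(state, "wb_cyto_state"))
  pop <- haplotype_pool(state)
  p_O <- sum(state$u)
  within <- if (p_O > 0) state$u / p_O else NULL
  list(population = pop / sum(pop), within_uninfected = within)
}

#' Iterate the joint infection / haplotype dynamics
#'
#' @param state0 Initial [cyto_state()].
#' @param params A [two_strain_params()] object.
#' @param n_gens Number of generations (>= 0).
#' @param paternal_leak Passed to [step_cyto()].
#' @return A data frame with columns `generation`, `p_A`, `p_R`, and one
#'   `u_<hap>` column per haplotype.
#' @examples
#' pars <- two_strain_params(1, 0, 1.08, 0.045, 0.55)
#' tr <- iterate_cyto(cyto_state(0, 0.2, c(A = 0, R = 0, anc = 0.8)), pars, 50)
#' tail(tr, 1)  # ancestral haplotype nearly swept out
#' @export
iterate_cyto <- function(state0, params, n_gens, paternal_leak = 0) {
  stopifnot(inherits(state0, "wb_cyto_state"))
  n_gens <- as.integer(n_gens)
  if (is.na(n_gens) || n_gens < 0L) stop("'n_gens' must be >= 0", call. = FALSE)
  haps <- names(state0$u)
  out <- matrix(NA_real_, nrow = n_gens + 1L, ncol = 2L + length(haps),
                dimnames = list(NULL, c("p_A", "p_R", paste0("u_", haps))))
  s <- state0
  out[1L, ] <- c(s$p_A, s$p_R, s$u)
  if (n_gens > 0L) for (t in seq_len(n_gens)) {
    s <- step_cyto(s, params, paternal_leak)
    out[t + 1L, ] <- c(s$p_A, s$p_R, s$u)
  }
  data.frame(generation = 0:n_gens, out)
}
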