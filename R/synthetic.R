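#' Design for a synthetic infection-frequency survey
#'
#' Describes a multi-site, multi-year survey whose expected frequencies
#' follow deterministic two-strain trajectories, with multinomial sampling
#' noise at each collection. This mirrors the structure of real field
#' surveys: a handful of sites, irregular sampling years, and a few
#' hundred flies typed per collection.
#'
#' @param sites A data frame with one row per site: columns `site` (label),
#'   `year0` (year of the site's generation-0 state), `p_A0`, `p_R0`
#'   (initial frequencies of the two strains).
#' @param years Integer vector of sampling years (each must be `>= year0`
#'   for every site sampled).
#' @param n Number of flies typed per site-year collection.
#' @param generations_per_year Host generations per calendar year.
#' @param params A [two_strain_params()] object driving all sites.
#' @param seed Integer seed; recorded in the design and honoured by
#'   [generate_survey()].
#' @return An object of class `wb_survey_design`.
#' @examples
#' pars <- two_strain_params(1.061, 0.023, 1.08, 0.045, 0.55)
#' des <- survey_design(
#'   sites = data.frame(site = "coast", year0 = 1994, p_A0 = 0.054, p_R0 = 0),
#'   years = c(1994, 2000, 2008), n = 200,
#'   generations_per_year = 20, params = pars, seed = 42)
#' @export
survey_design <- function(sites, years, n, generations_per_year, params,
                          seed = 1L) {
  sites <- as.data.frame(sites)
  need <- c("site", "year0", "p_A0", "p_R0")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("'sites' missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  stopifnot(inherits(params, "wb_two_strain_params"),
            is.numeric(years), length(years) >= 1L,
            is.numeric(n), n >= 1, generations_per_year > 0)
  years <- sort(years)
  if (any(vapply(seq_len(nrow(sites)), function(i)
    any(years < sites$year0[i]), logical(1))))
    stop("sampling year precedes a site's generation-0 year", call. = FALSE)
  structure(list(sites = sites, years = years, n = as.integer(n),
                 generations_per_year = generations_per_year,
                 params = params, seed = as.integer(seed)),
            class = "wb_survey_design")
}

#' Generate a synthetic survey table
#'
#' For each site, iterates the deterministic two-strain recursion from the
#' site's initial state, then draws the typed sample at each sampling year
#' as a multinomial over (wAu, wRi, uninfected) with probabilities equal
#' to the trajectory frequencies at that generation. Reproducible for a
#' fixed design seed; the global RNG state is left untouched.
#'
#' @param design A [survey_design()] object.
#' @return A survey data frame (columns `site`, `year`, `n_wAu`, `n_wRi`,
#'   `n_uninf`) with attribute `design` recording the design.
#' @examples
#' pars <- two_strain_params(1.061, 0.023, 1, 0, 1)
#' des <- survey_design(
#'   data.frame(site = "s1", year0 = 1994, p_A0 = 0.054, p_R0 = 0),
#'   years = c(1994, 2000), n = 100, generations_per_year = 20,
#'   params = pars, seed = 7)
#' generate_survey(des)
#' @export
generate_survey <- function(design) {
  stopifnot(inherits(design, "wb_survey_design"))
  rows <- local_rng(design$seed, {
    out <- vector("list", nrow(design$sites) * length(design$years))
    k <- 0L
    for (i in seq_len(nrow(design$sites))) {
      s <- design$sites[i, ]
      gens <- years_to_generations(design$years - s$year0,
                                   design$generations_per_year)
      traj <- iterate_two_strain(pop_state(s$p_A0, s$p_R0), design$params,
                                 max(gens))
      for (j in seq_along(design$years)) {
        pr <- as.numeric(traj[traj$generation == gens[j],
                              c("p_A", "p_R", "p_O")])
        cnt <- stats::rmultinom(1L, design$n, pr)[, 1L]
        k <- k + 1L
        out[[k]] <- data.frame(site = s$site, year = design$years[j],
                               n_wAu = cnt[1L], n_wRi = cnt[2L],
                               n_uninf = cnt[3L])
      }
    }
    do.call(rbind, out)
  })
  rownames(rows) <- NULL
  attr(rows, "design") <- design
  rows
}

#' Design for synthetic isofemale-line transmission data
#'
#' Each line is founded by one infected female; a per-line transmission
#' leakage is drawn from a beta distribution parameterized by its mean
#' `mu` and intra-class correlation `rho` (so `rho = 0` collapses to a
#' common leakage, i.e. pure binomial progeny counts), and the number of
#' uninfected progeny is binomial given the line's leakage. This
#' reproduces the across-female heterogeneity that motivates line-level
#' bootstrapping over the naive pooled binomial interval.
#'
#' @param n_lines Number of isofemale lines.
#' @param progeny_range Integer range (min, max) of progeny assayed per
#'   line; each line's count is uniform on this range.
#' @param mu Mean transmission leakage, in `[0, 1]`.
#' @param rho Intra-class correlation of the per-line leakage (>= 0, < 1);
#'   0 means no heterogeneity.
#' @param strain Mother strain label recorded in the table.
#' @param seed Integer seed.
#' @return An object of class `wb_line_design`.
#' @examples
#' line_design(n_lines = 34, progeny_range = c(10, 12), mu = 0.023,
#'             rho = 0.15, seed = 3)
#' @export
line_design <- function(n_lines, progeny_range = c(10, 12), mu,
                        rho = 0.15, strain = "wAu", seed = 1L) {
  n_lines <- as.integer(n_lines)
  stopifnot(n_lines >= 1L, length(progeny_range) == 2L,
            progeny_range[1] >= 1, progeny_range[2] >= progeny_range[1])
  mu <- check_freq(mu, "mu")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)", call. = FALSE)
  structure(list(n_lines = n_lines,
                 progeny_range = as.integer(progeny_range),
                 mu = mu, rho = rho, strain = strain,
                 seed = as.integer(seed)),
            class = "wb_line_design")
}

#' Generate a synthetic isofemale-line table
#'
#' @param design A [line_design()] object.
#' @return A line data frame (columns `line_id`, `mother_strain`,
#'   `n_progeny`, `n_infected`) with attribute `design`.
#' @examples
#' tab <- generate_lines(line_design(34, c(10, 12), mu = 0.023, seed = 3))
#' transmission_estimate(tab, n_boot = 200, seed = 3)$mu_hat
#' @export
generate_lines <- function(design) {
  stopifnot(inherits(design, "wb_line_design"))
  k <- design$n_lines
  tab <- local_rng(design$seed, {
    n_i <- sample(seq(design$progeny_range[1], design$progeny_range[2]),
                  k, replace = TRUE)
    q_i <- if (design$rho == 0 || design$mu %in% c(0, 1)) {
      rep(design$mu, k)
    } else {
      shape <- (1 - design$rho) / design$rho
      stats::rbeta(k, design$mu * shape, (1 - design$mu) * shape)
    }
    uninf <- stats::rbinom(k, n_i, q_i)
    data.frame(line_id = sprintf("L%03d", seq_len(k)),
               mother_strain = design$strain,
               n_progeny = n_i,
               n_infected = n_i - uninf)
  })
  attr(tab, "design") <- design
  tab
}
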