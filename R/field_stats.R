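#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Frequency estimate `x/n` with the exact two-sided interval whose
#' endpoints solve the binomial tail equations; computed via the beta
#' quantile representation. The lower limit is 0 exactly when `x = 0` and
#' the upper limit is 1 exactly when `x = n`.
#'
#' @param x Number of successes (infected flies, uninfected progeny, ...).
#' @param n Number of trials (> 0).
#' @param level Confidence level, default 0.95.
#' @return A named numeric vector `c(estimate, lower, upper)`.
#' @examples
#' binom_ci_exact(8, 350)    # transmission leakage 0.023 (0.010, 0.045)
#' binom_ci_exact(52, 92)    # infection frequency 0.565 (0.458, 0.669)
#' @export
binom_ci_exact <- function(x, n, level = 0.95) {
  stopifnot(is.numeric(x), is.numeric(n), length(x) == 1L, length(n) == 1L)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (x < 0 || x > n) stop("'x' must lie in [0, n]", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)", call. = FALSE)
  alpha <- 1 - level
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(estimate = x / n, lower = lower, upper = upper)
}

#' Pooled infection frequency from a survey table
#'
#' Sums counts over the selected survey rows before computing the estimate
#' and its exact binomial interval (pooling counts, not averaging
#' per-site frequencies).
#'
#' @param table A survey data frame as returned by [read_survey()] or
#'   [generate_survey()]: columns `site`, `year`, `n_wAu`, `n_wRi`,
#'   `n_uninf`.
#' @param strain Which infection to estimate the frequency of: `"wAu"`,
#'   `"wRi"` or `"uninfected"`.
#' @param rows Logical or integer index selecting rows (default: all).
#' @param level Confidence level.
#' @return A named numeric vector `c(estimate, lower, upper, x, n)`.
#' @examples
#' tab <- data.frame(site = c("a", "b"), year = 2008,
#'                   n_wAu = c(10, 30), n_wRi = c(5, 5), n_uninf = c(5, 5))
#' pooled_frequency(tab, "wAu")
#' @export
pooled_frequency <- function(table, strain = c("wAu", "wRi", "uninfected"),
                             rows = TRUE, level = 0.95) {
  strain <- match.arg(strain)
  table <- validate_survey(table)[rows, , drop = FALSE]
  if (!nrow(table)) stop("no survey rows selected", call. = FALSE)
  col <- switch(strain, wAu = "n_wAu", wRi = "n_wRi", uninfected = "n_uninf")
  x <- sum(table[[col]])
  n <- sum(table$n_wAu + table$n_wRi + table$n_uninf)
  c(binom_ci_exact(x, n, level), x = x, n = n)
}

#' G-test of independence / heterogeneity
#'
#' Log-likelihood-ratio test for a two-way contingency table (for example
#' sites by infection category): `G = 2 * sum(O * log(O / E))` with
#' expected counts from the row and column margins, `df = (r-1)(c-1)`, and
#' the p-value from the chi-square upper tail. Observed zeros contribute 0
#' to the sum. No Williams or Yates correction is applied. Rows or columns
#' whose margin is entirely zero are dropped with a warning.
#'
#' @param counts A numeric matrix (or object coercible to one) of
#'   non-negative counts, at least 2 x 2 after dropping empty margins.
#' @return An object of class `htest` with components `statistic` (G),
#'   `parameter` (df) and `p.value`.
#' @examples
#' m <- rbind(site1 = c(wRi = 10, wAu = 54, uninf = 36),
#'            site2 = c(12, 50, 38))
#' g_test(m)
#' @export
g_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) || any(!is.finite(counts)))
    stop("'counts' must be a matrix of non-negative finite counts", call. = FALSE)
  keep_r <- rowSums(counts) > 0
  keep_c <- colSums(counts) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping all-zero rows/columns from the contingency table")
    counts <- counts[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table after dropping empty margins",
         call. = FALSE)
  n <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  obs <- counts[counts > 0]
  G <- 2 * sum(obs * log(obs / expected[counts > 0]))
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  p <- stats::pchisq(G, df = df, lower.tail = FALSE)
  structure(list(statistic = c(G = G), parameter = c(df = df), p.value = p,
                 method = "Log-likelihood ratio (G) test of independence",
                 data.name = deparse(substitute(counts))),
            class = "htest")
}

#' Maternal transmission leakage from isofemale lines
#'
#' Pooled estimate of the transmission leakage `mu` (fraction of uninfected
#' progeny produced by infected mothers): total uninfected progeny divided
#' by total progeny, across lines. Two interval estimates are returned:
#' the exact binomial interval on the pooled counts, and a percentile
#' bootstrap interval obtained by resampling whole lines with replacement.
#' The line-level bootstrap respects heterogeneity in transmission rates
#' across females, which inflates the interval relative to the binomial
#' one when lines are overdispersed.
#'
#' @param lines A line table as returned by [read_line_table()] or
#'   [generate_lines()]: columns `line_id`, `mother_strain`, `n_progeny`,
#'   `n_infected`.
#' @param strain Optional mother strain to filter on (e.g. `"wAu"`);
#'   `NULL` uses all lines.
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed for the bootstrap resampling; recorded in the
#'   output. The global RNG state is left untouched.
#' @param level Confidence level.
#' @return A list with `mu_hat`, `binomial_ci`, `bootstrap_ci` (each a
#'   2-vector), `n_lines`, `n_progeny`, `n_uninfected`, `n_boot`, `seed`.
#' @examples
#' tab <- data.frame(line_id = paste0("L", 1:4), mother_strain = "wAu",
#'                   n_progeny = c(11, 10, 12, 10),
#'                   n_infected = c(11, 9, 12, 10))
#' transmission_estimate(tab, n_boot = 500, seed = 1)
#' @export
transmission_estimate <- function(lines, strain = NULL, n_boot = 10000L,
                                  seed = 1L, level = 0.95) {
  lines <- validate_lines(lines)
  if (!is.null(strain)) lines <- lines[lines$mother_strain == strain, , drop = FALSE]
  if (!nrow(lines)) stop("no lines selected", call. = FALSE)
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 1L) stop("'n_boot' must be >= 1", call. = FALSE)
  tot <- sum(lines$n_progeny)
  if (tot == 0) stop("zero total progeny", call. = FALSE)
  uninf <- lines$n_progeny - lines$n_infected
  mu_hat <- sum(uninf) / tot
  bci <- binom_ci_exact(sum(uninf), tot, level)
  k <- nrow(lines)
  boot <- local_rng(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(k, k, replace = TRUE)
      sum(uninf[idx]) / sum(lines$n_progeny[idx])
    }, numeric(1))
  })
  alpha <- 1 - level
  bootci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  list(mu_hat = mu_hat,
       binomial_ci = unname(bci[c("lower", "upper")]),
       bootstrap_ci = bootci,
       n_lines = k, n_progeny = tot, n_uninfected = sum(uninf),
       n_boot = n_boot, seed = seed)
}

# run expr under a private RNG stream, restoring global state afterwards
local_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

validate_survey <- function(table) {
  table <- as.data.frame(table)
  need <- c("site", "year", "n_wAu", "n_wRi", "n_uninf")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("survey table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cnt <- table[c("n_wAu", "n_wRi", "n_uninf")]
  if (any(!vapply(cnt, is.numeric, logical(1))) || any(unlist(cnt) < 0))
    stop("survey counts must be non-negative numbers", call. = FALSE)
  if (any(rowSums(cnt) <= 0))
    stop("every survey row must have a positive total count", call. = FALSE)
  table
}

validate_lines <- function(lines) {
  lines <- as.data.frame(lines)
  need <- c("line_id", "mother_strain", "n_progeny", "n_infected")
  miss <- setdiff(need, names(lines))
  if (length(miss))
    stop("line table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(lines$n_infected < 0) || any(lines$n_infected > lines$n_progeny))
    stop("need 0 <= n_infected <= n_progeny in every line", call. = FALSE)
  lines
}

#' Read a survey table from CSV
#'
#' Expects the header `site,year,n_wAu,n_wRi,n_uninf`.
#'
#' @param path Path to a CSV file.
#' @return A validated survey data frame.
#' @export
read_survey <- function(path) {
  validate_survey(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read an isofemale-line table from CSV
#'
#' Expects the header `line_id,mother_strain,n_progeny,n_infected`.
#'
#' @param path Path to a CSV file.
#' @return A validated line data frame.
#' @export
read_line_table <- function(path) {
  validate_lines(utils::read.csv(path, stringsAsFactors = FALSE))
}
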