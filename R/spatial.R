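#' One-dimensional deme lattice
#'
#' A stepping-stone habitat for contrasting bistable and Fisherian spatial
#' spread. Each deme holds a deterministic (infinite-population) frequency
#' state; demes exchange migrants with nearest neighbours at rate `m`, and
#' optional rare long-distance jumps (rate `lambda` events per generation,
#' uniform source and destination) model human-mediated dispersal.
#'
#' @param n_demes Number of demes (>= 2).
#' @param states Either a single [pop_state()] used for every deme, or a
#'   numeric matrix with `n_demes` rows and columns `p_A`, `p_R`, `p_O`.
#' @param m Migration rate to each nearest neighbour, in `[0, 0.5]`.
#' @param lambda Expected number of long-distance jump events per
#'   generation (>= 0).
#' @param jump_frac Fraction of the destination deme replaced by migrants
#'   from the source deme during a jump event.
#' @return An object of class `wb_lattice`.
#' @examples
#' lat <- lattice_init(50, pop_state(0, 0), m = 0.1)
#' @export
lattice_init <- function(n_demes, states, m = 0.1, lambda = 0,
                         jump_frac = 0.05) {
  n_demes <- as.integer(n_demes)
  stopifnot(n_demes >= 2L)
  if (!is.numeric(m) || m < 0 || m > 0.5)
    stop("'m' must lie in [0, 0.5]", call. = FALSE)
  if (lambda < 0) stop("'lambda' must be >= 0", call. = FALSE)
  if (inherits(states, "wb_pop_state")) {
    states <- matrix(unclass(states), nrow = n_demes, ncol = 3L, byrow = TRUE,
                     dimnames = list(NULL, c("p_A", "p_R", "p_O")))
  } else {
    states <- as.matrix(states)
    stopifnot(nrow(states) == n_demes, ncol(states) == 3L)
    colnames(states) <- c("p_A", "p_R", "p_O")
    if (any(abs(rowSums(states) - 1) > 1e-8))
      stop("each deme state must sum to 1", call. = FALSE)
  }
  structure(list(n_demes = n_demes, states = states, m = m,
                 lambda = lambda, jump_frac = jump_frac),
            class = "wb_lattice")
}

#' Set the state of selected demes
#'
#' @param lat A [lattice_init()] object.
#' @param demes Integer indices of demes to overwrite.
#' @param state A [pop_state()] applied to each selected deme.
#' @return The modified lattice.
#' @export
lattice_set <- function(lat, demes, state) {
  stopifnot(inherits(lat, "wb_lattice"), inherits(state, "wb_pop_state"))
  lat$states[demes, ] <- matrix(unclass(state), nrow = length(demes),
                                ncol = 3L, byrow = TRUE)
  lat
}

#' One generation of the lattice dynamics
#'
#' Deterministic nearest-neighbour migration (reflecting boundaries: edge
#' demes exchange only with their single neighbour), then the local
#' two-strain recursion [step_two_strain()] in every deme, then any
#' long-distance jump events (stochastic; supply `rng = TRUE` after
#' seeding, or use [run_lattice()] which seeds explicitly).
#'
#' @param lat A [lattice_init()] object.
#' @param params A [two_strain_params()] object.
#' @return The lattice one generation later.
#' @examples
#' lat <- lattice_init(10, pop_state(0, 0.5), m = 0)
#' lat2 <- step_lattice(lat, two_strain_params(1, 0, 1.08, 0.045, 0.55))
#' @export
step_lattice <- function(lat, params) {
  stopifnot(inherits(lat, "wb_lattice"),
            inherits(params, "wb_two_strain_params"))
  x <- lat$states
  n <- lat$n_demes
  m <- lat$m
  if (m > 0) {
    left <- x[c(1L, seq_len(n - 1L)), , drop = FALSE]
    right <- x[c(seq_len(n)[-1L], n), , drop = FALSE]
    # reflecting: the self-copy at each edge cancels one emigration term
    x <- (1 - 2 * m) * x + m * left + m * right
  }
  for (i in seq_len(n)) {
    s <- pop_state(x[i, 1L], x[i, 2L], x[i, 3L])
    x[i, ] <- unclass(step_two_strain(s, params))
  }
  if (lat$lambda > 0) {
    n_jumps <- stats::rpois(1L, lat$lambda)
    if (n_jumps > 0) for (j in seq_len(n_jumps)) {
      src <- sample.int(n, 1L)
      dst <- sample.int(n, 1L)
      x[dst, ] <- (1 - lat$jump_frac) * x[dst, ] + lat$jump_frac * x[src, ]
    }
  }
  lat$states <- x
  lat
}

#' Run the lattice for many generations
#'
#' @param lat A [lattice_init()] object.
#' @param params A [two_strain_params()] object.
#' @param n_gens Number of generations.
#' @param seed Integer seed for jump events (ignored when `lambda = 0`,
#'   but still applied for reproducibility).
#' @param record_every Record a snapshot every this many generations
#'   (generation 0 and the final generation are always recorded).
#' @return A list with `lattice` (final state) and `snapshots`, a long
#'   data frame with columns `generation`, `deme`, `p_A`, `p_R`, `p_O`.
#' @examples
#' pars <- two_strain_params(1, 0, 1.1, 0.045, 0.55)
#' lat <- lattice_set(lattice_init(30, pop_state(0, 0), m = 0.1), 1,
#'                    pop_state(0, 0.9))
#' run <- run_lattice(lat, pars, 50, seed = 1, record_every = 10)
#' @export
run_lattice <- function(lat, params, n_gens, seed = 1L, record_every = 1L) {
  stopifnot(inherits(lat, "wb_lattice"))
  n_gens <- as.integer(n_gens)
  if (is.na(n_gens) || n_gens < 0L) stop("'n_gens' must be >= 0", call. = FALSE)
  snap <- function(gen, l) data.frame(generation = gen,
                                      deme = seq_len(l$n_demes), l$states)
  snaps <- list(snap(0L, lat))
  local_rng(seed, {
    if (n_gens > 0L) for (t in seq_len(n_gens)) {
      lat <- step_lattice(lat, params)
      if (t %% record_every == 0L || t == n_gens)
        snaps[[length(snaps) + 1L]] <- snap(t, lat)
    }
  })
  list(lattice = lat, snapshots = do.call(rbind, snaps))
}

#' Position of the invasion front
#'
#' @param lat A [lattice_init()] object.
#' @param threshold Frequency defining "invaded", in (0, 1).
#' @param strain `"R"` (default) or `"A"`.
#' @return Largest deme index whose focal-strain frequency is at least
#'   `threshold`, or `NA_integer_` when no deme qualifies.
#' @export
front_position <- function(lat, threshold = 0.5, strain = c("R", "A")) {
  stopifnot(inherits(lat, "wb_lattice"))
  strain <- match.arg(strain)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  col <- if (strain == "R") "p_R" else "p_A"
  idx <- which(lat$states[, col] >= threshold)
  if (!length(idx)) NA_integer_ else max(idx)
}
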