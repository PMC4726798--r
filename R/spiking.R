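# Stage 1: per-stimulus saliency plus top-down spatial bias set the initial
# firing rates of Poisson populations, which then evolve under all-to-all
# competitive inhibition. Stimuli are represented at the population-rate
# level (inhibition proportional to competitors' instantaneous rates) with
# per-neuron spikes drawn from the rate trajectory.

#' Initial firing rate of a stimulus population
#'
#' Maps a bottom-up saliency value linearly onto a firing rate, damps the
#' sensory drive by local crowding (surround suppression at encoding: each
#' near neighbor reduces an item's drive by a Gaussian-weighted fraction),
#' and adds the top-down spatial priming signal, `f/N` Hz, for items inside
#' the primed region (`N` = number of primed locations, so a single cued
#' location gets the full `f`). Spatial and saliency contributions are
#' additive; the result is capped.
#'
#' @param s Saliency in `[0, 1]`.
#' @param primed Logical: does the item lie in the primed region?
#' @param n_primed Number of primed locations (`N >= 1` when priming applies).
#' @param crowding Per-item crowding index (sum of Gaussian distance
#'   weights to the other items; see [crowding_index()]), 0 for isolated.
#' @param config Model configuration.
#' @return Firing rate in Hz.
#' @export
initial_rate <- function(s, primed, n_primed = 1L, crowding = 0,
                         config = default_config()) {
  sp <- config$spiking
  if (any(s < 0)) stop("saliency must be non-negative", call. = FALSE)
  if (any(primed) && n_primed < 1) stop("n_primed must be >= 1", call. = FALSE)
  damp <- pmax(0, 1 - sp$crowd_kappa * crowding)
  r <- sp$r_min + (sp$r_max - sp$r_min) * s * damp +
    ifelse(primed, sp$f / n_primed, 0)
  pmin(r, sp$r_cap)
}

#' Crowding index of each item in a display
#'
#' Sum of Gaussian distance weights to all other items,
#' `sum_j exp(-d_ij^2 / (2 sigma^2))`: 0 for an isolated item, larger for
#' an item surrounded by near neighbors (e.g. a distractor at the center of
#' the search array).
#'
#' @param display A `display_spec`.
#' @param config Model configuration (`crowd_sigma`, px).
#' @return Numeric vector, one value per item.
#' @export
crowding_index <- function(display, config = default_config()) {
  it <- display$items
  sigma <- config$spiking$crowd_sigma
  n <- nrow(it)
  if (n <= 1) return(rep(0, n))
  d2 <- outer(it$x, it$x, `-`)^2 + outer(it$y, it$y, `-`)^2
  w <- exp(-d2 / (2 * sigma^2))
  diag(w) <- 0
  rowSums(w)
}

# Per-bin firing hazard corrected for the absolute refractory period, so the
# realized long-run rate matches the nominal rate r (valid for r well below
# 1000/t_ref).
refractory_hazard <- function(r, t_ref) {
  p <- r / 1000
  pmin(0.95, p / pmax(1e-12, 1 - r * t_ref / 1000))
}

#' Generate a stimulus population of Poisson spike trains
#'
#' `M` independent Poisson spike trains at rate `r` with an absolute
#' refractory period; the hazard is corrected so the realized mean rate
#' equals the nominal rate. Identical seeds give identical populations.
#'
#' @param r Rate in Hz (`r = 0` yields empty trains).
#' @param M Number of neurons.
#' @param T Duration in ms.
#' @param seed Integer seed.
#' @param config Model configuration (refractory period, time step).
#' @return A `spike_population`: list with `trains` (list of strictly
#'   increasing spike-time vectors in `[0, T)`), `r`, `M`, `T`.
#' @export
generate_population <- function(r, M, T, seed, config = default_config()) {
  stopifnot(r >= 0, T > 0, M >= 1)
  sp <- config$spiking
  trains <- with_seed(seed, {
    lapply(seq_len(M), function(i) {
      if (r <= 0) return(numeric(0))
      mean_gap <- 1000 / r
      exp_mean <- mean_gap - sp$t_ref
      if (exp_mean <= 0) exp_mean <- 1e-3
      # stationary start: first spike from the equilibrium recurrence-time
      # distribution of the shifted-exponential interval, so the expected
      # count over [0, T) is exactly r * T
      first <- if (stats::runif(1) < sp$t_ref / mean_gap) {
        stats::runif(1) * sp$t_ref
      } else {
        sp$t_ref + stats::rexp(1, rate = 1 / exp_mean)
      }
      n_max <- ceiling(T / mean_gap * 3 + 20)
      gaps <- sp$t_ref + stats::rexp(n_max, rate = 1 / exp_mean)
      times <- cumsum(c(first, gaps))
      times[times < T]
    })
  })
  structure(list(trains = trains, r = r, M = M, T = T),
            class = "spike_population")
}

#' @export
print.spike_population <- function(x, ...) {
  n <- vapply(x$trains, length, integer(1))
  cat("<spike_population> M =", x$M, " T =", x$T, "ms  nominal r =", x$r,
      "Hz  empirical r =", round(mean(n) / x$T * 1000, 2), "Hz\n")
  invisible(x)
}

#' Mean firing rate of a population
#'
#' @param population A `spike_population`.
#' @return Mean spikes per second across member trains.
#' @export
population_rate <- function(population) {
  mean(vapply(population$trains, length, integer(1))) / population$T * 1000
}

#' Create a competition state
#'
#' @param rates Initial per-item rates (Hz).
#' @param input Per-item input (attractor) rates; defaults to `rates`.
#' @param config Model configuration (`lambda`, `w_inh`).
#' @return A `competition_state` list.
#' @export
competition_state <- function(rates, input = rates,
                              config = default_config()) {
  stopifnot(all(rates >= 0), length(input) == length(rates))
  structure(list(r = rates, input = input,
                 lambda = config$spiking$lambda,
                 w_inh = config$spiking$w_inh),
            class = "competition_state")
}

#' One step of competitive rate dynamics
#'
#' Each item's rate relaxes toward its input rate while receiving inhibition
#' proportional to the summed instantaneous rates of all competitors, so
#' more active stimuli suppress others more strongly:
#' `r_i <- max(0, r_i + dt * (-lambda (r_i - input_i) - w_inh * sum_{j != i} r_j))`.
#'
#' @param state A `competition_state`.
#' @param dt Time step in ms (must be positive).
#' @return The updated state.
#' @export
step_competition <- function(state, dt) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  tot <- sum(state$r)
  state$r <- pmax(0, state$r + dt * (-state$lambda * (state$r - state$input) -
                                       state$w_inh * (tot - state$r)))
  state
}

# Integrate the competition over n steps, returning the item x step rate
# trajectory (used by the trial engine window loop).
run_competition <- function(rates, input, n_steps, dt, lambda, w_inh) {
  traj <- matrix(0, length(rates), n_steps)
  r <- rates
  for (k in seq_len(n_steps)) {
    tot <- sum(r)
    r <- pmax(0, r + dt * (-lambda * (r - input) - w_inh * (tot - r)))
    traj[, k] <- r
  }
  traj
}

#' Leaky integrate-and-fire unit
#'
#' Standard leaky IF: the membrane potential decays with time constant
#' `tau`, jumps by the input weight per incoming spike, and emits a spike
#' and resets on crossing the threshold, with an absolute refractory period.
#'
#' @param inputs List of spike-time vectors (shared duration `T`).
#' @param weights Per-input weights (recycled).
#' @param theta Firing threshold (must be positive).
#' @param tau Membrane time constant, ms.
#' @param dt Integration step, ms.
#' @param T Duration, ms (defaults to the latest input spike, rounded up).
#' @param t_ref Refractory period, ms.
#' @return Vector of output spike times.
#' @export
integrate_and_fire <- function(inputs, weights = 1, theta, tau, dt = 1,
                               T = NULL, t_ref = 2) {
  if (theta <= 0) stop("theta must be positive", call. = FALSE)
  if (is.null(T)) {
    T <- max(c(1, unlist(inputs)), na.rm = TRUE)
    T <- ceiling(T) + 1
  }
  weights <- rep_len(weights, length(inputs))
  n_bins <- ceiling(T / dt)
  drive <- numeric(n_bins)
  for (i in seq_along(inputs)) {
    b <- floor(inputs[[i]] / dt) + 1
    b <- b[b >= 1 & b <= n_bins]
    for (bb in b) drive[bb] <- drive[bb] + weights[i]
  }
  v <- 0; out <- numeric(0); refr <- 0
  decay <- exp(-dt / tau)
  for (k in seq_len(n_bins)) {
    if (refr > 0) { refr <- refr - dt; v <- 0; next }
    v <- v * decay + drive[k]
    if (v >= theta) {
      out <- c(out, k * dt)
      v <- 0
      refr <- t_ref
    }
  }
  out
}
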