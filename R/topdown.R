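# Stage 2: feature-based top-down modulation. Target templates are regular
# spike trains held in the Endogenous Module; a similarity-gated temporal
# filter pulls stimulus spikes toward template spike times (synchronization
# without changing spike counts), and a control module of coincidence
# detector (CD) nodes converts the resulting stimulus-template synchrony
# into a multiplicative rate gain.

#' Feature similarity between two letter identities
#'
#' Symmetric lookup: 1 for identical letters, a high value for letters in
#' the same angular shape family as the targets (the confusable high-load
#' flankers), and a low value otherwise (e.g. O vs X).
#'
#' @param a,b Letter identities from the glyph set.
#' @param config Model configuration (`sim_high`, `sim_low`, family).
#' @return Score in `[0, 1]`.
#' @export
feature_similarity <- function(a, b, config = default_config()) {
  td <- config$topdown
  known <- glyph_set()
  if (!a %in% known || !b %in% known) {
    stop("unknown identity: ", paste(setdiff(c(a, b), known), collapse = ", "),
         call. = FALSE)
  }
  if (a == b) return(1)
  if (a %in% td$angular_letters && b %in% td$angular_letters) return(td$sim_high)
  td$sim_low
}

#' Target template spike train
#'
#' Templates have a fixed internal temporal structure: a regular (periodic)
#' train at `r_template` Hz spanning the trial, phase-centered so each
#' period carries one spike at its midpoint.
#'
#' @param identity Target letter (carried as an attribute).
#' @param T Trial duration, ms.
#' @param config Model configuration.
#' @return Numeric vector of spike times with attributes `identity`, `T`.
#' @export
target_template <- function(identity, T, config = default_config()) {
  period <- 1000 / config$topdown$r_template
  times <- seq(period / 2, T - 1e-9, by = period)
  attr(times, "identity") <- identity
  attr(times, "T") <- T
  times
}

# Pull spike times toward the nearest template spike by fraction alpha of
# the gap, with displacement capped; order and per-train spike count are
# preserved, and a minimal inter-spike gap is enforced.
pull_spikes <- function(times, template, alpha, shift_max, t_ref, T) {
  if (length(times) == 0 || length(template) == 0) return(times)
  idx <- findInterval(times, template)
  lo <- pmax(idx, 1); hi <- pmin(idx + 1, length(template))
  d_lo <- abs(times - template[lo]); d_hi <- abs(template[hi] - times)
  nearest <- ifelse(d_lo <= d_hi, template[lo], template[hi])
  shift <- alpha * (nearest - times)
  shift <- pmax(pmin(shift, shift_max), -shift_max)
  out <- sort(times + shift)
  if (length(out) > 1) {
    for (i in 2:length(out)) {
      if (out[i] < out[i - 1] + t_ref) out[i] <- out[i - 1] + t_ref
    }
  }
  eps <- 1e-6
  if (out[length(out)] >= T) {
    out <- pmin(out, T - eps - (length(out) - seq_along(out)) * t_ref)
    out <- cummax(out)
  }
  pmax(out, 0)
}

#' Similarity-gated temporal filter
#'
#' If the stimulus-template similarity reaches the gate threshold, every
#' spike in every member train is moved toward the nearest template spike
#' by a fraction `alpha` of the gap (displacement capped), preserving spike
#' order, refractoriness, and -- exactly -- the spike count per train, so
#' the mean firing rate is unchanged. Below the threshold the population is
#' returned bit-identical.
#'
#' @param population A `spike_population`.
#' @param template A [target_template()] of the same duration.
#' @param similarity Score from [feature_similarity()].
#' @param config Model configuration (`rho0`, `alpha`, `shift_max`, `t_ref`).
#' @return The filtered `spike_population`.
#' @export
temporal_filter <- function(population, template, similarity,
                            config = default_config()) {
  td <- config$topdown
  if (!is.null(attr(template, "T")) &&
      abs(attr(template, "T") - population$T) > 1e-9) {
    stop("template and population durations differ", call. = FALSE)
  }
  if (similarity < td$rho0) return(population)
  population$trains <- lapply(population$trains, pull_spikes,
                              template = as.numeric(template),
                              alpha = td$alpha, shift_max = td$shift_max,
                              t_ref = config$spiking$t_ref, T = population$T)
  population
}

#' Construct a coincidence-detector node
#'
#' Each CD node listens to exactly three spike trains: two neurons sampled
#' (without replacement) from the stimulus population and the target
#' template; it fires when at least two of the three carry a spike within
#' the coincidence window.
#'
#' @param population_trains List of the stimulus population's spike trains.
#' @param template A [target_template()].
#' @param neurons Integer pair: indices of the two sampled neurons.
#' @return A `cd_node` list.
#' @export
cd_node <- function(population_trains, template, neurons) {
  stopifnot(length(neurons) == 2, !anyDuplicated(neurons))
  structure(list(trains = list(population_trains[[neurons[1]]],
                               population_trains[[neurons[2]]],
                               as.numeric(template)),
                 neurons = as.integer(neurons), k = 2L),
            class = "cd_node")
}

#' Does a CD node fire at time t?
#'
#' `TRUE` iff at least two of the node's three input trains contain a spike
#' within `[t - delta/2, t + delta/2]`.
#'
#' @param node A [cd_node()].
#' @param t Query time in ms, within `[0, T)`.
#' @param delta Coincidence window, ms.
#' @param T Trial duration used for the range check (optional).
#' @return Logical.
#' @export
cd_fire <- function(node, t, delta = default_config()$topdown$delta, T = NULL) {
  if (t < 0 || (!is.null(T) && t >= T)) {
    stop("t outside [0, T)", call. = FALSE)
  }
  hits <- vapply(node$trains, function(tr) {
    any(tr >= t - delta / 2 & tr <= t + delta / 2)
  }, logical(1))
  sum(hits) >= node$k
}

#' Control signal gain from CD population activity
#'
#' The control module's amplification is proportional to the per-node CD
#' firing rate, scaled by the stimulus-template similarity (the degree of
#' amplification depends on how closely the stimulus resembles the target):
#' `g = min(g_max, 1 + similarity * gamma * total_rate / n_nodes)`. A
#' silent CD population gives `g = 1`; the gain is non-decreasing in the
#' firing count, in `gamma`, and in `similarity`, and is applied
#' multiplicatively to the stimulus input rate in the next competition
#' step.
#'
#' @param fire_count Total CD firings in the window (across nodes).
#' @param n_nodes Number of CD nodes.
#' @param window Window length, ms.
#' @param similarity Stimulus-template similarity in `[0, 1]`.
#' @param config Model configuration (`gamma`, `g_max`).
#' @return Gain `g >= 1`.
#' @export
control_gain <- function(fire_count, n_nodes, window, similarity = 1,
                         config = default_config()) {
  stopifnot(fire_count >= 0, n_nodes >= 1, window > 0)
  td <- config$topdown
  rate_per_node <- fire_count / n_nodes / (window / 1000)  # Hz
  min(td$g_max, 1 + similarity * td$gamma * rate_per_node)
}
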