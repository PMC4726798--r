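# Working-memory readout: a deliberately simple two-node network over the
# two response alternatives. The task is a letter report (X vs N), so the
# evidence stream for each alternative pools the spikes of every stimulus
# population carrying that letter -- a compatible distractor adds to the
# target's own evidence, an incompatible one drives the competing
# alternative. Node 1 integrates the pooled spikes of whichever alternative
# currently leads; node 2 integrates node-1 spikes (helped by a recurrent
# node-2 -> node-1 drive) and its first spike marks perceptual awareness.
# The report is correct when the leading alternative at that moment carries
# the target letter.

#' Run the working-memory readout for one trial
#'
#' @param pooled Matrix of pooled spike counts, items x time bins (one
#'   column per `dt`), i.e. summed spikes of each stimulus population.
#' @param items Item tibble (`display$items`): `id`, `identity`, `role`.
#' @param target_identity The letter to be reported.
#' @param config Model configuration (`decision` block).
#' @return A one-row tibble: `responded`, `correct`, `latency` (ms, `NA`
#'   when no response), `winner_id`, `winner_identity`, `winner_role`.
#'   `winner_id`/`winner_role` identify the stimulus that contributed most
#'   to the winning alternative's evidence around the response.
#' @export
wm_run <- function(pooled, items, target_identity,
                   config = default_config()) {
  if (is.null(dim(pooled)) || nrow(pooled) == 0) {
    stop("empty population set", call. = FALSE)
  }
  dc <- config$decision
  dt <- config$spiking$dt
  n_bins <- ncol(pooled)

  letters_resp <- target_letters()
  ev <- do.call(rbind, lapply(letters_resp, function(L) {
    rows <- which(items$identity == L)
    if (!length(rows)) return(rep(0, n_bins))
    colSums(pooled[rows, , drop = FALSE])
  }))

  # smoothed evidence -> instantaneous leading alternative
  sm <- matrix(0, nrow(ev), n_bins)
  decay_s <- exp(-dt / dc$smooth_tau)
  acc <- numeric(nrow(ev))
  for (k in seq_len(n_bins)) {
    acc <- acc * decay_s + ev[, k]
    sm[, k] <- acc
  }
  leader <- max.col(t(sm), ties.method = "first")

  decay1 <- exp(-dt / dc$tau1); decay2 <- exp(-dt / dc$tau2)
  v1 <- 0; v2 <- 0; refr1 <- 0
  response_bin <- NA_integer_
  for (k in seq_len(n_bins)) {
    drive <- ev[leader[k], k] * dc$w_in + dc$w_r * v2 / dc$theta2
    if (refr1 > 0) {
      refr1 <- refr1 - dt; v1 <- 0
      s1 <- 0
    } else {
      v1 <- v1 * decay1 + drive
      s1 <- if (v1 >= dc$theta1) 1 else 0
      if (s1 > 0) { v1 <- 0; refr1 <- dc$t_ref }
    }
    v2 <- v2 * decay2 + dc$w_12 * s1
    if (v2 >= dc$theta2) { response_bin <- k; break }
  }

  if (is.na(response_bin)) {
    return(tibble::tibble(responded = FALSE, correct = FALSE,
                          latency = NA_real_, winner_id = NA_character_,
                          winner_identity = NA_character_,
                          winner_role = NA_character_))
  }
  # winning alternative: modal leader over the attribution window; the
  # winning stimulus is its strongest contributor there
  win_lo <- max(1, response_bin - round(dc$winner_window / dt) + 1)
  tab <- tabulate(leader[win_lo:response_bin], nbins = nrow(ev))
  w_letter <- letters_resp[which.max(tab)]
  rows <- which(items$identity == w_letter)
  contrib <- rowSums(pooled[rows, win_lo:response_bin, drop = FALSE])
  w_item <- rows[which.max(contrib)]
  tibble::tibble(
    responded = TRUE,
    correct = w_letter == target_identity,
    latency = response_bin * dt + dc$latency_offset,
    winner_id = items$id[w_item],
    winner_identity = w_letter,
    winner_role = items$role[w_item])
}
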