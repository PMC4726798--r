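# One simulated trial: display -> saliency -> initial rates (+ spatial
# priming) -> windowed stage-1/stage-2 loop (competitive rate dynamics,
# Poisson spiking, similarity-gated temporal filtering, CD-based gain)
# -> working-memory readout.

#' Run one simulated trial
#'
#' Executes the complete processing pipeline for one display. The trial is
#' integrated in windows of one template period: within each window the
#' population rates evolve under competitive inhibition (with the control
#' gains from the previous window multiplying each stimulus' input rate),
#' spikes are drawn from the rate trajectories, spike times of
#' target-resembling stimuli are pulled toward the template rhythm, and the
#' coincidence-detector population converts the achieved synchrony into the
#' next window's gain. Pooled population spikes drive the working-memory
#' readout.
#'
#' @param display A `display_spec` from [build_display()].
#' @param saliency Per-item saliency tibble from [stimulus_saliency()]
#'   (computed from the rendered display when omitted).
#' @param seed Integer seed for all trial-level randomness.
#' @param config Model configuration.
#' @return A list: `result` (one-row tibble as [wm_run()] plus bookkeeping),
#'   `rates` (item x bin rate trajectory), `gains` (item x window),
#'   `cd_counts` (item x window), `saliency`, `initial_rates`.
#' @export
run_trial <- function(display, saliency = NULL, seed = 1L,
                      config = default_config()) {
  sp <- config$spiking; td <- config$topdown
  items <- display$items
  n_items <- nrow(items)
  if (is.null(saliency)) {
    map <- compute_saliency_map(render_display(display), config)
    saliency <- stimulus_saliency(map, item_masks(display, config), items)
  }
  s <- saliency$s[match(items$id, saliency$id)]

  primed <- in_region(display$task_region, items$x, items$y)
  n_primed <- display$task_region$n_locations
  r0 <- initial_rate(s, primed, n_primed, crowding_index(display, config),
                     config)

  target_identity <- items$identity[items$role == "target"]
  templates <- lapply(target_letters(), target_template, T = sp$T,
                      config = config)
  names(templates) <- target_letters()
  sims <- vapply(items$identity, function(id) {
    v <- vapply(target_letters(), feature_similarity, numeric(1), b = id,
                config = config)
    c(v[which.max(v)], which.max(v))
  }, numeric(2))
  best_sim <- sims[1, ]
  best_tpl <- target_letters()[sims[2, ]]

  window <- 1000 / td$r_template          # one template period, ms
  w_bins <- round(window / sp$dt)
  n_win <- floor(sp$T / window)
  n_bins <- n_win * w_bins
  tpl_bin <- round(w_bins / 2)            # template spike at window center

  # CD input assignment: per item, n_cd nodes each with 2 distinct neurons
  cd_a <- cd_b <- matrix(0L, td$n_cd, n_items)
  with_seed(derive_seed(seed, "cd"), {
    for (i in seq_len(n_items)) {
      for (n in seq_len(td$n_cd)) {
        pick <- sample.int(sp$M, 2)
        cd_a[n, i] <- pick[1]; cd_b[n, i] <- pick[2]
      }
    }
  })

  pooled <- matrix(0, n_items, n_bins)
  rates <- matrix(0, n_items, n_bins)
  gains <- matrix(1, n_items, n_win)
  cd_counts <- matrix(0, n_items, n_win)
  g <- rep(1, n_items)
  r_cur <- r0
  tsls <- matrix(sp$t_ref, sp$M, n_items)  # time since last spike, per neuron

  with_seed(derive_seed(seed, "trial"), {
    for (w in seq_len(n_win)) {
      gains[, w] <- g
      traj <- run_competition(r_cur, pmin(g * r0, sp$r_cap), w_bins, sp$dt,
                              sp$lambda, sp$w_inh)
      r_cur <- traj[, w_bins]
      bin0 <- (w - 1) * w_bins
      rates[, bin0 + seq_len(w_bins)] <- traj

      for (i in seq_len(n_items)) {
        haz <- refractory_hazard(traj[i, ], sp$t_ref)
        spk <- matrix(FALSE, w_bins, sp$M)
        u <- matrix(stats::runif(w_bins * sp$M), w_bins, sp$M)
        for (k in seq_len(w_bins)) {
          can <- tsls[, i] >= sp$t_ref
          fired <- can & (u[k, ] < haz[k])
          spk[k, ] <- fired
          tsls[, i] <- ifelse(fired, 0, tsls[, i] + sp$dt)
        }
        if (best_sim[i] >= td$rho0 && any(spk)) {
          spk <- shift_binned_spikes(spk, tpl_bin, td$alpha, td$shift_max,
                                     sp$dt)
        }
        # CD evaluation: >= 2 of {neuron a, neuron b, template} spiking
        # within the coincidence window (delta, centered)
        half <- floor(td$delta / sp$dt / 2)
        d <- dilate_bins(spk, half)
        tpl_ind <- rep(FALSE, w_bins); tpl_ind[tpl_bin] <- TRUE
        tpl_d <- dilate_bins(matrix(tpl_ind, ncol = 1), half)[, 1]
        fires <- (d[, cd_a[, i]] + d[, cd_b[, i]] + tpl_d) >= 2
        cd_counts[i, w] <- sum(fires)
        pooled[i, bin0 + seq_len(w_bins)] <- rowSums(spk)
      }
      # competition is driven by the populations' actual spiking: the next
      # window starts from each population's realized rate, so Poisson
      # variability propagates through the inhibitory loop
      r_cur <- rowSums(pooled[, bin0 + seq_len(w_bins), drop = FALSE]) /
        (sp$M * window) * 1000
      g <- vapply(seq_len(n_items), function(i) {
        control_gain(cd_counts[i, w], td$n_cd, window, best_sim[i], config)
      }, numeric(1))
    }
  })

  res <- wm_run(pooled, items, target_identity, config)
  res$target_identity <- target_identity
  res$seed <- seed
  list(result = res, rates = rates, gains = gains, cd_counts = cd_counts,
       saliency = saliency, initial_rates = r0, pooled = pooled)
}

# Move binned spikes toward the template bin by fraction alpha of the gap
# (displacement capped); spike counts are preserved exactly.
shift_binned_spikes <- function(spk, tpl_bin, alpha, shift_max, dt) {
  w_bins <- nrow(spk)
  idx <- which(spk, arr.ind = TRUE)
  shift <- round(alpha * (tpl_bin - idx[, 1]))
  cap <- round(shift_max / dt)
  shift <- pmax(pmin(shift, cap), -cap)
  new_bin <- pmin(pmax(idx[, 1] + shift, 1), w_bins)
  out <- matrix(FALSE, w_bins, ncol(spk))
  for (j in seq_len(nrow(idx))) {
    b <- new_bin[j]; cc <- idx[j, 2]
    while (out[b, cc] && b < w_bins) b <- b + 1L   # keep per-neuron count
    out[b, cc] <- TRUE
  }
  out
}

# Binary dilation of spike indicators along time by +-half bins.
dilate_bins <- function(m, half) {
  if (half <= 0) return(m)
  out <- m
  n <- nrow(m)
  for (s in seq_len(half)) {
    out[seq_len(n - s), ] <- out[seq_len(n - s), ] | m[(s + 1):n, ]
    out[(s + 1):n, ] <- out[(s + 1):n, ] | m[seq_len(n - s), ]
  }
  out
}
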