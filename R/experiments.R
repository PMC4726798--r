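# The four simulated studies: condition registries, trial batches,
# condition summaries, and distractor-interference scores with a
# permutation noise floor.

#' Conditions of a named experiment
#'
#' Returns the condition list of one of the four simulated studies:
#' * `basic_load` -- 2 loads x 3 compatibilities, peripheral distractor;
#' * `cueing` -- 2 loads x cued/uncued x compatible/incompatible;
#' * `central_distractor` -- central/peripheral x 2 loads x
#'   compatible/incompatible;
#' * `dilution` -- low-load/low-dilution, low-load/high-dilution,
#'   high-load/high-dilution x compatible/incompatible (colored square
#'   arrays).
#'
#' @param name Experiment name.
#' @return Named list of [condition_spec()] objects.
#' @export
experiment_conditions <- function(name = c("basic_load", "cueing",
                                           "central_distractor", "dilution")) {
  name <- match.arg(name)
  conds <- switch(
    name,
    basic_load = {
      grid <- expand.grid(load = c("low", "high"),
                          compatibility = c("compatible", "incompatible",
                                            "neutral"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i) {
        condition_spec(paste("basic", grid$load[i], grid$compatibility[i],
                             sep = "_"),
                       grid$load[i], grid$compatibility[i], "peripheral")
      })
    },
    cueing = {
      grid <- expand.grid(load = c("low", "high"),
                          compatibility = c("compatible", "incompatible"),
                          cued = c(FALSE, TRUE), stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i) {
        condition_spec(paste("cueing",
                             ifelse(grid$cued[i], "cued", "uncued"),
                             grid$load[i], grid$compatibility[i], sep = "_"),
                       grid$load[i], grid$compatibility[i], "peripheral",
                       cued = grid$cued[i])
      })
    },
    central_distractor = {
      grid <- expand.grid(load = c("low", "high"),
                          compatibility = c("compatible", "incompatible"),
                          position = c("peripheral", "central"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i) {
        condition_spec(paste("central", grid$position[i], grid$load[i],
                             grid$compatibility[i], sep = "_"),
                       grid$load[i], grid$compatibility[i], grid$position[i])
      })
    },
    dilution = {
      grid <- expand.grid(cell = c("low_low", "low_high", "high_high"),
                          compatibility = c("compatible", "incompatible"),
                          stringsAsFactors = FALSE)
      lapply(seq_len(nrow(grid)), function(i) {
        parts <- strsplit(grid$cell[i], "_")[[1]]
        condition_spec(paste("dilution", grid$cell[i], grid$compatibility[i],
                             sep = "_"),
                       parts[1], grid$compatibility[i], "peripheral",
                       dilution = parts[2])
      })
    })
  names(conds) <- vapply(conds, `[[`, character(1), "name")
  conds
}

#' Run all trials of one condition
#'
#' Runs `n` simulated trials of a condition with deterministic
#' counterbalancing: target identity (X/N) and array slot cycle through all
#' combinations, and the peripheral distractor side alternates. Each trial
#' seed is derived from the master seed, the condition name, and the trial
#' index, so the same call always reproduces the same trial table.
#' Saliency maps are cached per unique display.
#'
#' @param condition A [condition_spec()].
#' @param n Number of trials.
#' @param master_seed Integer master seed.
#' @param config Model configuration.
#' @param cache Optional environment reused across conditions to cache
#'   per-display saliency tables.
#' @return A tibble of per-trial results (one row each).
#' @export
run_condition <- function(condition, n = 50L, master_seed = 1L,
                          config = default_config(),
                          cache = new.env(parent = emptyenv())) {
  n_slots <- if (condition$dilution == "n/a") 6L else 4L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- derive_seed(master_seed, condition$name, i)
    tid <- target_letters()[(i - 1L) %% 2L + 1L]
    slot <- ((i - 1L) %/% 2L) %% n_slots
    side <- if (((i - 1L) %/% (2L * n_slots)) %% 2L == 0L) -1 else 1
    display <- build_display(condition, tid, slot, seed_i, config,
                             side = side)
    sig <- display_signature(display)
    sal <- cache[[sig]]
    if (is.null(sal)) {
      map <- compute_saliency_map(render_display(display), config)
      sal <- stimulus_saliency(map, item_masks(display, config),
                               display$items)
      cache[[sig]] <- sal
    }
    out <- run_trial(display, sal, seed = seed_i, config = config)
    row <- out$result
    row$condition <- condition$name
    row$trial <- i
    rows[[i]] <- row
  }
  dplyr::bind_rows(rows)
}

#' Summarize the trials of one condition
#'
#' Median latency is computed over correct responded trials (the usual
#' reaction-time convention); omission and accuracy are reported alongside.
#'
#' @param trials Trial tibble from [run_condition()].
#' @return One-row tibble: `condition`, `n`, `n_correct`, `median_latency`,
#'   `accuracy`, `omission_rate`.
#' @export
summarize_condition <- function(trials) {
  ok <- trials$responded & trials$correct
  tibble::tibble(
    condition = trials$condition[1],
    n = nrow(trials),
    n_correct = sum(ok),
    median_latency = if (any(ok)) stats::median(trials$latency[ok]) else NA_real_,
    accuracy = mean(trials$correct),
    omission_rate = mean(!trials$responded))
}

#' Distractor interference between two conditions
#'
#' The compatibility effect: median latency of the incompatible condition
#' minus median latency of the matching compatible condition, in ms.
#'
#' @param trials_incompatible,trials_compatible Trial tibbles of the paired
#'   conditions.
#' @return Signed difference in ms.
#' @export
interference <- function(trials_incompatible, trials_compatible) {
  li <- correct_latencies(trials_incompatible)
  lc <- correct_latencies(trials_compatible)
  if (!length(li) || !length(lc)) {
    stop("interference undefined: a condition has no correct responses",
         call. = FALSE)
  }
  stats::median(li) - stats::median(lc)
}

correct_latencies <- function(trials) {
  trials$latency[trials$responded & trials$correct]
}

#' Permutation noise floor for an interference score
#'
#' Estimates the spread of the median-difference statistic under a
#' zero-effect pairing: correct latencies of the two conditions are pooled
#' and repeatedly re-split at the original sizes; the 2.5% and 97.5%
#' quantiles of the resulting differences delimit the noise floor. An
#' observed interference outside this interval exceeds the simulation's
#' noise; one inside it is indistinguishable from zero.
#'
#' @param trials_incompatible,trials_compatible Paired trial tibbles.
#' @param n_boot Number of resamples.
#' @param seed Seed for the resampling.
#' @return Named vector `c(lo, hi)` in ms.
#' @export
noise_floor <- function(trials_incompatible, trials_compatible,
                        n_boot = 1000L, seed = 1L) {
  li <- correct_latencies(trials_incompatible)
  lc <- correct_latencies(trials_compatible)
  pool <- c(li, lc)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(pool), length(li))
      stats::median(pool[idx]) - stats::median(pool[-idx])
    }, numeric(1))
  })
  stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
}

interference_pairs <- function(name) {
  switch(name,
    basic_load = list(
      basic_low = c("basic_low_incompatible", "basic_low_compatible"),
      basic_high = c("basic_high_incompatible", "basic_high_compatible")),
    cueing = list(
      uncued_low = c("cueing_uncued_low_incompatible",
                     "cueing_uncued_low_compatible"),
      uncued_high = c("cueing_uncued_high_incompatible",
                      "cueing_uncued_high_compatible"),
      cued_low = c("cueing_cued_low_incompatible",
                   "cueing_cued_low_compatible"),
      cued_high = c("cueing_cued_high_incompatible",
                    "cueing_cued_high_compatible")),
    central_distractor = list(
      peripheral_low = c("central_peripheral_low_incompatible",
                         "central_peripheral_low_compatible"),
      peripheral_high = c("central_peripheral_high_incompatible",
                          "central_peripheral_high_compatible"),
      central_low = c("central_central_low_incompatible",
                      "central_central_low_compatible"),
      central_high = c("central_central_high_incompatible",
                       "central_central_high_compatible")),
    dilution = list(
      dilution_low_low = c("dilution_low_low_incompatible",
                           "dilution_low_low_compatible"),
      dilution_low_high = c("dilution_low_high_incompatible",
                            "dilution_low_high_compatible"),
      dilution_high_high = c("dilution_high_high_incompatible",
                             "dilution_high_high_compatible")))
}

#' Run a full simulated experiment
#'
#' Runs every condition of the named experiment, summarizes each, and
#' computes all defined interference scores with their permutation noise
#' floors.
#'
#' @param name One of `"basic_load"`, `"cueing"`, `"central_distractor"`,
#'   `"dilution"`.
#' @param trials Trials per condition.
#' @param master_seed Integer master seed for the whole experiment.
#' @param config Model configuration.
#' @return A `load_experiment` object: list with `name`, `summaries`
#'   (tibble), `interference` (tibble with noise-floor bounds), `trials`
#'   (all raw trials), `config`, `master_seed`.
#' @export
run_experiment <- function(name, trials = 50L, master_seed = 1L,
                           config = default_config()) {
  conds <- experiment_conditions(name)
  cache <- new.env(parent = emptyenv())
  trial_tbls <- lapply(conds, run_condition, n = trials,
                       master_seed = master_seed, config = config,
                       cache = cache)
  summaries <- dplyr::bind_rows(lapply(trial_tbls, summarize_condition))

  pairs <- interference_pairs(name)
  infs <- lapply(names(pairs), function(lbl) {
    p <- pairs[[lbl]]
    ti <- trial_tbls[[p[1]]]; tc <- trial_tbls[[p[2]]]
    if (!length(correct_latencies(ti)) || !length(correct_latencies(tc))) {
      warning("no correct responses in cell ", lbl, "; interference undefined")
      return(tibble::tibble(cell = lbl, interference = NA_real_,
                            floor_lo = NA_real_, floor_hi = NA_real_,
                            exceeds_floor = NA))
    }
    fl <- noise_floor(ti, tc, config$experiments$n_boot,
                      seed = derive_seed(master_seed, lbl))
    val <- interference(ti, tc)
    tibble::tibble(cell = lbl, interference = val,
                   floor_lo = fl[1], floor_hi = fl[2],
                   exceeds_floor = val > fl[2])
  })

  structure(
    list(name = name, summaries = summaries,
         interference = dplyr::bind_rows(infs),
         trials = dplyr::bind_rows(trial_tbls),
         config = config, master_seed = master_seed),
    class = "load_experiment")
}

#' @export
print.load_experiment <- function(x, ...) {
  cat("<load_experiment>", x$name, " (", max(x$summaries$n),
      "trials/condition, master seed", x$master_seed, ")\n\n")
  print(as.data.frame(x$summaries), digits = 4, row.names = FALSE)
  cat("\nInterference (incompatible - compatible, ms):\n")
  print(as.data.frame(x$interference), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a full experiment report to a directory
#'
#' Writes the configuration echo, the trial table, the condition summaries,
#' and the interference table as delimited text under `dir`.
#'
#' @param experiment A `load_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config(experiment$config, file.path(dir, "config.yaml"))
  utils::write.csv(experiment$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$summaries, file.path(dir, "summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$interference,
                   file.path(dir, "interference.csv"), row.names = FALSE)
  writeLines(c(paste("experiment:", experiment$name),
               paste("master_seed:", experiment$master_seed)),
             file.path(dir, "run.txt"))
  invisible(dir)
}
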