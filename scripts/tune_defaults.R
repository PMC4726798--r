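# Coarse grid search used to pick the shipped defaults for the competitive
# inhibition weight (w_inh) and the control-module gain (gamma). One global
# parameter set must satisfy the qualitative pattern of all four simulated
# studies simultaneously, so the search scores the basic-load pattern
# (fast low load, slow high load, interference only in low load) on a
# reduced trial count and the winners are then checked against the full
# pattern suite (tests/testthat/test-acceptance.R).
#
#   Rscript scripts/tune_defaults.R [n_trials]

suppressPackageStartupMessages(library(loadsim))
n <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(n)) n <- 30L

cache <- new.env(parent = emptyenv())
conds <- list(
  condition_spec("basic_low_compatible", "low", "compatible"),
  condition_spec("basic_low_incompatible", "low", "incompatible"),
  condition_spec("basic_high_compatible", "high", "compatible"),
  condition_spec("basic_high_incompatible", "high", "incompatible"))

for (w in c(0.012, 0.016, 0.020, 0.024)) {
  for (g in c(0.012, 0.02, 0.03)) {
    cfg <- default_config()
    cfg$spiking$w_inh <- w
    cfg$topdown$gamma <- g
    tt <- lapply(conds, run_condition, n = n, master_seed = 1,
                 config = cfg, cache = cache)
    names(tt) <- vapply(conds, `[[`, character(1), "name")
    s <- vapply(tt, function(tr) {
      summarize_condition(tr)$median_latency
    }, numeric(1))
    i_low <- interference(tt$basic_low_incompatible, tt$basic_low_compatible)
    i_high <- interference(tt$basic_high_incompatible, tt$basic_high_compatible)
    load_effect <- mean(s[3:4]) - mean(s[1:2])
    score <- (load_effect > 20) + (i_low > 20) + (abs(i_high) < 20)
    cat(sprintf(
      "w_inh=%.4f gamma=%.3f | medians %s | int low %+.0f high %+.0f | score %d/3\n",
      w, g, paste(round(s), collapse = "/"), i_low, i_high, score))
  }
}
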