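# Shared fixtures: a small config for fast dynamics tests and cached
# displays/saliency for the standard conditions.

fast_config <- function(...) {
  cfg <- default_config()
  cfg$spiking$T <- 200
  cfg$topdown$n_cd <- 10L
  deep_merge_test(cfg, list(...))
}

deep_merge_test <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      deep_merge_test(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

# saliency tables are deterministic per display; cache across tests
.sal_cache <- new.env(parent = emptyenv())

cached_saliency <- function(display, config = default_config()) {
  key <- loadsim:::display_signature(display)
  out <- .sal_cache[[key]]
  if (is.null(out)) {
    map <- compute_saliency_map(render_display(display), config)
    out <- stimulus_saliency(map, item_masks(display, config),
                             display$items)
    .sal_cache[[key]] <- out
  }
  out
}

with_seed_test <- function(seed, code) loadsim:::with_seed(seed, code)

basic_condition <- function(load, compatibility, position = "peripheral",
                            cued = FALSE) {
  condition_spec(paste("t", load, compatibility, position, sep = "_"),
                 load, compatibility, position, cued = cued)
}
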