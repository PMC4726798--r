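#' Default model configuration
#'
#' Returns the full set of constants controlling display geometry, the
#' saliency pipeline, stage-1 spiking dynamics, the stage-2 control module,
#' and the working-memory readout. Every value can be overridden through
#' [load_config()] or by editing the returned list; all simulation entry
#' points accept a `config` argument.
#'
#' Times are milliseconds, rates Hz, pixel units px, colors RGB in `[0, 1]`.
#'
#' @return A named nested list of parameters.
#' @export
default_config <- function() {
  list(
    display = list(
      canvas = c(256L, 256L),            # width, height in px
      background = c(0, 0, 0),
      letter_color = c(0.8, 0.8, 0.8),
      array_radius = 50,                 # circular search array radius
      glyph_height = 20,                 # target/flanker glyph height
      distractor_height = 30,            # larger to-be-ignored distractor
      peripheral_offset = 115,           # distractor eccentricity from center
      square_half = 45,                  # half-side of the 4-letter square
      neutral_identity = "P",
      high_load_letters = c("K", "M", "V", "W", "Z", "H"),
      dilution_letters = c("S", "C", "T"),
      color_red = c(0.85, 0.10, 0.10),
      color_green = c(0.10, 0.80, 0.10),
      color_white = c(1, 1, 1),
      mask_margin = 2                    # dilation of per-item masks, px
    ),
    saliency = list(
      map_level = 2L,                    # map at 1/2^map_level resolution
      center_scales = c(2L, 3L, 4L),
      surround_deltas = c(3L, 4L),
      n_levels = 8L,                     # pyramid depth (level 0 = input)
      n_orientations = 4L,
      gabor_size = 19L,
      semisat = 0.45,                     # semisaturation constant of the map nonlinearity
      local_max_thresh = 0.06,           # peaks below this ignored in weighting
      compete_iter = 0L                  # within-map competition iterations
    ),
    spiking = list(
      M = 20L,                           # neurons per stimulus population
      T = 500,                           # trial duration, ms
      dt = 1,                            # integration step, ms
      r_min = 5,                         # rate at zero saliency, Hz
      r_max = 60,                        # rate at unit saliency, Hz
      r_cap = 200,                       # hard ceiling after biases, Hz
      f = 120,                           # top-down spatial signal base rate, Hz
      t_ref = 2,                         # absolute refractory period, ms
      lambda = 0.04,                     # rate relaxation constant, 1/ms
      w_inh = 0.020,                     # all-to-all competitive inhibition
      crowd_kappa = 0.08,                # sensory crowding suppression per neighbor
      crowd_sigma = 60                   # crowding interaction range, px
    ),
    topdown = list(
      delta = 3,                         # CD coincidence window, ms
      alpha = 0.5,                       # temporal-filter pull fraction
      rho0 = 0.5,                        # similarity gate for the filter
      shift_max = 6,                     # max spike displacement, ms
      n_cd = 40L,                        # CD nodes per stimulus
      gamma = 0.030,                     # control gain per Hz of CD activity
      g_max = 2,                         # gain ceiling
      r_template = 40,                   # template train rate, Hz (periodic)
      continuous = TRUE,                 # re-apply filter every window
      sim_high = 0.7,                    # confusable letters (shape family)
      sim_low = 0.1,                     # dissimilar letters
      angular_letters = c("X", "N", "K", "M", "V", "W", "Z", "H")
    ),
    decision = list(
      tau1 = 20,                         # node-1 membrane constant, ms
      theta1 = 20,                       # node-1 threshold
      w_in = 1,                          # weight per pooled input spike
      tau2 = 200,                        # node-2 membrane constant, ms
      theta2 = 8,                        # node-2 (awareness) threshold
      w_12 = 1,                          # node-1 spike -> node-2 weight
      w_r = 1,                           # recurrent node-2 -> node-1 drive
      t_ref = 2,                         # node refractory period, ms
      smooth_tau = 20,                   # leader-rate smoothing constant, ms
      winner_window = 50,                # window for winner attribution, ms
      latency_offset = 0                 # optional calibration offset, ms
    ),
    experiments = list(
      trials = 50L,                      # trials per condition
      n_boot = 1000L                     # permutation resamples for noise floor
    )
  )
}

deep_merge <- function(base, override) {
  if (!is.list(override)) return(override)
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      deep_merge(base[[nm]], override[[nm]])
    } else {
      override[[nm]]
    }
  }
  base
}

#' Load a configuration file
#'
#' Reads a YAML document of parameter overrides and merges it over
#' [default_config()]. Unspecified values keep their defaults, so a config
#' file only needs to list the constants it changes.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list merged over the file contents.
#' @return A full configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    stopifnot(file.exists(path))
    cfg <- deep_merge(cfg, yaml::read_yaml(path))
  }
  deep_merge(cfg, overrides)
}

#' Write a configuration to YAML
#'
#' @param config A configuration list (see [default_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Deterministic 31-bit seed from a master seed, a label, and an index.
# Plain polynomial string hash; keeps derived seeds below 2^31.
derive_seed <- function(master, label, i = 0L) {
  mod <- 2147483647
  h <- as.numeric(master) %% mod
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% mod
  }
  h <- (h * 31 + as.numeric(i) * 2654435761) %% mod
  as.integer(max(1, h %% (mod - 1)))
}

# Evaluate code under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
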