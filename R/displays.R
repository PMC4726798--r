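#' Define an experimental condition
#'
#' A condition names one cell of a load/flanker experiment: the nominal
#' perceptual load of the search array, the compatibility of the
#' to-be-ignored distractor with the target letter, where that distractor
#' appears, the dilution cell (for the colored 4-letter task), and whether
#' the target location is cued ahead of the display.
#'
#' `load` and `dilution` are display-construction labels only: the model has
#' no load parameter, and which cell behaves as "high load" emerges from the
#' saliency and competition dynamics.
#'
#' @param name Condition label used in seeds, tables and reports.
#' @param load `"low"` or `"high"`.
#' @param compatibility `"compatible"`, `"incompatible"` or `"neutral"`.
#' @param distractor_position `"peripheral"`, `"central"` or `"none"`.
#' @param dilution `"n/a"`, `"low"` or `"high"` (the dilution tasks use a
#'   4-letter square array; `"n/a"` selects the 6-item circular array).
#' @param cued `TRUE` if a 100%-valid cue primes the target location.
#' @return A `condition_spec` object.
#' @export
condition_spec <- function(name, load, compatibility,
                           distractor_position = "peripheral",
                           dilution = "n/a", cued = FALSE) {
  load <- match.arg(load, c("low", "high"))
  compatibility <- match.arg(compatibility,
                             c("compatible", "incompatible", "neutral"))
  distractor_position <- match.arg(distractor_position,
                                   c("peripheral", "central", "none"))
  dilution <- match.arg(as.character(dilution), c("n/a", "low", "high"))
  if (dilution != "n/a" && distractor_position == "central") {
    stop("dilution conditions use a peripheral distractor", call. = FALSE)
  }
  if (dilution != "n/a" && cued) {
    stop("dilution conditions are uncued", call. = FALSE)
  }
  if (dilution == "low" && load == "high") {
    stop("the high-load/low-dilution cell is not part of the design",
         call. = FALSE)
  }
  structure(
    list(name = name, load = load, compatibility = compatibility,
         distractor_position = distractor_position, dilution = dilution,
         cued = cued),
    class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat("<condition_spec>", x$name, "\n")
  cat("  load:", x$load, " compatibility:", x$compatibility, "\n")
  cat("  distractor:", x$distractor_position, " dilution:", x$dilution,
      " cued:", x$cued, "\n")
  invisible(x)
}

target_letters <- function() c("X", "N")

distractor_identity <- function(compatibility, target_identity, config) {
  switch(compatibility,
         compatible = target_identity,
         incompatible = setdiff(target_letters(), target_identity)[1],
         neutral = config$display$neutral_identity)
}

#' Build a display specification for one trial
#'
#' Constructs the declarative description of a single search display:
#' item identities, roles, pixel positions, glyph sizes and colors, the
#' task-relevant region primed by instructions (or by the cue), and the
#' canvas. Load conditions use a 6-slot circular array of letters with a
#' larger distractor letter left/right of (or centered in) the array;
#' dilution conditions use colored letters at the 4 corners of an imaginary
#' square with a larger white distractor adjacent to the array.
#'
#' The same `(condition, target_identity, target_slot, seed)` always yields
#' an identical display.
#'
#' @param condition A [condition_spec()].
#' @param target_identity `"X"` or `"N"`.
#' @param target_slot 0-based array position (0..5 circular, 0..3 square).
#' @param seed Integer controlling flanker draw, distractor side and (for
#'   dilution) the target color.
#' @param config Model configuration, see [default_config()].
#' @param side Optional override of the peripheral distractor side
#'   (`-1` left, `+1` right); defaults to a seed-derived choice.
#' @return A `display_spec` object: a list with `items` (tibble), `canvas`,
#'   `background`, `task_region`, `cue`, and `condition`.
#' @export
build_display <- function(condition, target_identity, target_slot, seed,
                          config = default_config(), side = NULL) {
  stopifnot(inherits(condition, "condition_spec"))
  if (!target_identity %in% target_letters()) {
    stop("target identity must be one of ", paste(target_letters(), collapse = "/"),
         call. = FALSE)
  }
  dc <- config$display
  cx <- (dc$canvas[1] - 1) / 2
  cy <- (dc$canvas[2] - 1) / 2
  if (is.null(side)) side <- if (seed %% 2L == 0L) -1 else 1

  if (condition$dilution == "n/a") {
    display <- build_circular_display(condition, target_identity, target_slot,
                                      seed, dc, cx, cy, side)
  } else {
    display <- build_dilution_display(condition, target_identity, target_slot,
                                      seed, dc, cx, cy, side)
  }
  display$condition <- condition
  display$cue <- if (condition$cued) {
    tgt <- display$items[display$items$role == "target", ]
    c(tgt$x, tgt$y)
  } else NULL
  if (condition$cued) {
    display$task_region <- list(kind = "point",
                                center = display$cue,
                                n_locations = 1L)
  }
  validate_display(display)
  display
}

build_circular_display <- function(condition, target_identity, target_slot,
                                   seed, dc, cx, cy, side) {
  if (!target_slot %in% 0:5) stop("circular arrays have slots 0..5", call. = FALSE)
  ang <- (-90 + 60 * (0:5)) * pi / 180
  sx <- cx + dc$array_radius * cos(ang)
  sy <- cy + dc$array_radius * sin(ang)

  if (condition$load == "low") {
    flankers <- rep("O", 5)
  } else {
    flankers <- with_seed(seed, sample(dc$high_load_letters, 5))
  }
  ids <- character(6); ids[target_slot + 1] <- target_identity
  ids[ids == ""] <- flankers
  roles <- ifelse(seq_len(6) == target_slot + 1, "target", "flanker")

  items <- tibble::tibble(
    id = paste0("item", seq_len(6)),
    identity = ids, role = roles, x = sx, y = sy,
    size = dc$glyph_height,
    r = dc$letter_color[1], g = dc$letter_color[2], b = dc$letter_color[3])

  n_loc <- 6L
  if (condition$distractor_position != "none") {
    d_id <- distractor_identity(condition$compatibility, target_identity, dc_cfg(dc))
    if (condition$distractor_position == "peripheral") {
      dx <- cx + side * dc$peripheral_offset; dy <- cy
    } else {
      dx <- cx; dy <- cy
      n_loc <- 7L
    }
    items <- dplyr::bind_rows(items, tibble::tibble(
      id = "distractor", identity = d_id, role = "distractor",
      x = dx, y = dy, size = dc$distractor_height,
      r = dc$letter_color[1], g = dc$letter_color[2], b = dc$letter_color[3]))
  }

  list(items = items,
       canvas = dc$canvas, background = dc$background,
       task_region = list(kind = "disk", center = c(cx, cy),
                          radius = dc$array_radius + dc$glyph_height,
                          n_locations = n_loc),
       cue = NULL)
}

build_dilution_display <- function(condition, target_identity, target_slot,
                                   seed, dc, cx, cy, side) {
  if (!target_slot %in% 0:3) stop("square arrays have slots 0..3", call. = FALSE)
  h <- dc$square_half
  sx <- cx + c(-h, h, h, -h)
  sy <- cy + c(-h, -h, h, h)
  tgt_red <- ((seed %/% 2L) %% 2L) == 0L
  tcol <- if (tgt_red) dc$color_red else dc$color_green
  fcol <- if (condition$dilution == "high" && condition$load == "high") {
    tcol                                    # high-load/high-dilution: same color
  } else {
    if (tgt_red) dc$color_green else dc$color_red
  }

  items <- tibble::tibble(
    id = "item1", identity = target_identity, role = "target",
    x = sx[target_slot + 1], y = sy[target_slot + 1],
    size = dc$glyph_height, r = tcol[1], g = tcol[2], b = tcol[3])

  with_flankers <- !(condition$dilution == "low" && condition$load == "low")
  if (with_flankers) {
    fl_slots <- setdiff(0:3, target_slot)
    fl_ids <- with_seed(seed, sample(dc$dilution_letters, 3))
    items <- dplyr::bind_rows(items, tibble::tibble(
      id = paste0("item", 2:4), identity = fl_ids, role = "flanker",
      x = sx[fl_slots + 1], y = sy[fl_slots + 1],
      size = dc$glyph_height, r = fcol[1], g = fcol[2], b = fcol[3]))
  }

  d_id <- distractor_identity(condition$compatibility, target_identity, dc_cfg(dc))
  items <- dplyr::bind_rows(items, tibble::tibble(
    id = "distractor", identity = d_id, role = "distractor",
    x = cx + side * dc$peripheral_offset, y = cy,
    size = dc$distractor_height,
    r = dc$color_white[1], g = dc$color_white[2], b = dc$color_white[3]))

  list(items = items,
       canvas = dc$canvas, background = dc$background,
       task_region = list(kind = "rect", center = c(cx, cy),
                          half = h + dc$glyph_height, n_locations = 4L),
       cue = NULL)
}

# wrap a display-config sublist so distractor_identity can reuse it
dc_cfg <- function(dc) list(display = dc)

validate_display <- function(display) {
  it <- display$items
  if (sum(it$role == "target") != 1) stop("exactly one target required", call. = FALSE)
  if (sum(it$role == "distractor") > 1) stop("at most one distractor", call. = FALSE)
  if (any(it$role == "distractor")) {
    dsz <- it$size[it$role == "distractor"]
    if (any(dsz <= it$size[it$role != "distractor"])) {
      stop("distractor must be strictly larger than target/flankers", call. = FALSE)
    }
  }
  w <- display$canvas[1]; h <- display$canvas[2]
  if (any(it$x < 0 | it$x > w - 1 | it$y < 0 | it$y > h - 1)) {
    stop("item centers must lie within the canvas", call. = FALSE)
  }
  tgt <- it[it$role == "target", ]
  if (!in_region(display$task_region, tgt$x, tgt$y)) {
    stop("target center must lie within the task region", call. = FALSE)
  }
  if (!is.null(display$cue) &&
      (abs(display$cue[1] - tgt$x) > 1e-9 || abs(display$cue[2] - tgt$y) > 1e-9)) {
    stop("cues are 100% valid: cue must equal the target center", call. = FALSE)
  }
  invisible(display)
}

in_region <- function(region, x, y) {
  switch(region$kind,
         disk = sqrt((x - region$center[1])^2 + (y - region$center[2])^2) <=
           region$radius + 1e-9,
         rect = abs(x - region$center[1]) <= region$half + 1e-9 &
           abs(y - region$center[2]) <= region$half + 1e-9,
         point = abs(x - region$center[1]) < 1e-6 &
           abs(y - region$center[2]) < 1e-6)
}

# glyph footprint of one item as a logical canvas matrix (rows = y, cols = x)
glyph_footprint <- function(item, canvas) {
  bm <- glyph_bitmap(item$identity, item$size)
  m <- matrix(FALSE, canvas[2], canvas[1])
  top <- round(item$y - nrow(bm) / 2)
  left <- round(item$x - ncol(bm) / 2)
  rr <- (top + 1):(top + nrow(bm))
  cc <- (left + 1):(left + ncol(bm))
  keep_r <- rr >= 1 & rr <= canvas[2]
  keep_c <- cc >= 1 & cc <= canvas[1]
  m[rr[keep_r], cc[keep_c]] <- bm[keep_r, keep_c, drop = FALSE] > 0
  m
}

#' Render a display to an RGB pixel grid
#'
#' Deterministically rasterizes every item's glyph, scaled to its size and
#' painted in its color, over the background. Coordinates are 0-based,
#' origin top-left.
#'
#' @param display A `display_spec` from [build_display()].
#' @return A numeric array `height x width x 3` with values in `[0, 1]`.
#' @export
render_display <- function(display) {
  w <- display$canvas[1]; h <- display$canvas[2]
  img <- array(rep(display$background, each = w * h), dim = c(h, w, 3))
  for (i in seq_len(nrow(display$items))) {
    item <- display$items[i, ]
    fp <- glyph_footprint(item, display$canvas)
    col <- c(item$r, item$g, item$b)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[fp] <- col[ch]
      img[, , ch] <- plane
    }
  }
  img
}

#' Per-item pixel masks
#'
#' Returns one logical mask per item covering its glyph footprint plus a
#' small dilation margin, used to read per-stimulus values off the saliency
#' map. Raw glyph footprints must not overlap (an error reports the pair);
#' where only the dilation margins of two items touch, the contested pixels
#' are dropped from both so masks stay disjoint.
#'
#' @param display A `display_spec`.
#' @param config Model configuration (mask margin).
#' @return Named list of logical matrices (one per item id).
#' @export
item_masks <- function(display, config = default_config()) {
  margin <- config$display$mask_margin
  raw <- lapply(seq_len(nrow(display$items)), function(i) {
    glyph_footprint(display$items[i, ], display$canvas)
  })
  names(raw) <- display$items$id
  overlap_tot <- Reduce(`+`, lapply(raw, function(m) m * 1L))
  if (any(overlap_tot > 1L)) {
    bad <- which(overlap_tot > 1L, arr.ind = TRUE)[1, ]
    pair <- names(raw)[vapply(raw, function(m) m[bad[1], bad[2]], logical(1))]
    stop("overlapping glyphs: ", paste(pair, collapse = " and "), call. = FALSE)
  }
  brush <- EBImage::makeBrush(2L * margin + 1L, shape = "box")
  dil <- lapply(raw, function(m) EBImage::dilate(m * 1, brush) > 0)
  tot <- Reduce(`+`, lapply(dil, function(m) m * 1L))
  contested <- tot > 1L
  if (any(contested)) {
    dil <- Map(function(d, r) (d & !contested) | r, dil, raw)
  }
  names(dil) <- display$items$id
  dil
}

display_signature <- function(display) {
  it <- display$items
  paste(c(paste(it$identity, it$role, round(it$x, 2), round(it$y, 2), it$size,
                round(it$r, 3), round(it$g, 3), round(it$b, 3),
                sep = ":", collapse = "|"),
          paste(display$canvas, collapse = "x"),
          paste(round(display$background, 3), collapse = ",")),
        collapse = "#")
}

#' Write a display specification to a YAML document
#'
#' One document per display: condition fields, canvas, background, task
#' region, optional cue, and the item table.
#'
#' @param display A `display_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_display <- function(display, path) {
  doc <- list(
    condition = unclass(display$condition),
    canvas = as.integer(display$canvas),
    background = as.numeric(display$background),
    task_region = display$task_region,
    cue = if (is.null(display$cue)) NULL else as.numeric(display$cue),
    items = lapply(seq_len(nrow(display$items)), function(i) {
      as.list(display$items[i, ])
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a display specification written by [write_display()]
#'
#' @param path Path to the YAML document.
#' @return A `display_spec` object.
#' @export
read_display <- function(path) {
  doc <- yaml::read_yaml(path)
  cond <- do.call(condition_spec, doc$condition)
  display <- list(
    items = dplyr::bind_rows(lapply(doc$items, tibble::as_tibble)),
    canvas = as.integer(doc$canvas),
    background = as.numeric(doc$background),
    task_region = doc$task_region,
    cue = if (is.null(doc$cue)) NULL else as.numeric(doc$cue),
    condition = cond)
  validate_display(display)
  display
}

#' Export a rendered display as PNG
#'
#' @param display A `display_spec`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_display_png <- function(display, path) {
  png::writePNG(render_display(display), path)
  invisible(path)
}
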