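test_that("condition constructor validates field combinations", {
  expect_s3_class(condition_spec("a", "low", "incompatible"), "condition_spec")
  expect_error(condition_spec("a", "high", "compatible", dilution = "low"),
               "high-load/low-dilution")
  expect_error(condition_spec("a", "low", "compatible", "central",
                              dilution = "high"), "peripheral")
  expect_error(condition_spec("a", "low", "oops"))
})

test_that("built displays satisfy the structural invariants", {
  cfg <- default_config()
  conds <- list(
    basic_condition("low", "incompatible"),
    basic_condition("high", "compatible"),
    basic_condition("high", "neutral", "central"),
    condition_spec("dl", "low", "incompatible", dilution = "low"),
    condition_spec("dh", "high", "incompatible", dilution = "high"))
  for (cn in conds) {
    slot_max <- if (cn$dilution == "n/a") 5 else 3
    for (slot in c(0, slot_max)) {
      d <- build_display(cn, "X", slot, seed = 7, config = cfg)
      it <- d$items
      expect_equal(sum(it$role == "target"), 1)
      expect_lte(sum(it$role == "distractor"), 1)
      dsz <- it$size[it$role == "distractor"]
      expect_true(all(dsz > it$size[it$role != "distractor"]))
      expect_true(all(it$x >= 0 & it$x <= d$canvas[1] - 1))
      tgt <- it[it$role == "target", ]
      expect_true(loadsim:::in_region(d$task_region, tgt$x, tgt$y))
    }
  }
})

test_that("distractor identity follows the compatibility rule", {
  cfg <- default_config()
  for (tid in c("X", "N")) {
    d_c <- build_display(basic_condition("low", "compatible"), tid, 0, 3, cfg)
    d_i <- build_display(basic_condition("low", "incompatible"), tid, 0, 3, cfg)
    d_n <- build_display(basic_condition("low", "neutral"), tid, 0, 3, cfg)
    did <- function(d) d$items$identity[d$items$role == "distractor"]
    expect_identical(did(d_c), tid)
    expect_identical(did(d_i), setdiff(c("X", "N"), tid))
    expect_identical(did(d_n), cfg$display$neutral_identity)
    expect_false(did(d_n) %in% c("X", "N"))
  }
})

test_that("display construction is deterministic and seed-sensitive", {
  cn <- basic_condition("high", "incompatible")
  d1 <- build_display(cn, "X", 2, seed = 11)
  d2 <- build_display(cn, "X", 2, seed = 11)
  d3 <- build_display(cn, "X", 2, seed = 12)
  expect_identical(d1$items, d2$items)
  expect_false(identical(d1$items$identity, d3$items$identity) &&
                 identical(d1$items$x, d3$items$x))
})

test_that("low-load flankers are all O; high-load flankers are letters", {
  low <- build_display(basic_condition("low", "neutral"), "N", 1, 5)
  expect_true(all(low$items$identity[low$items$role == "flanker"] == "O"))
  high <- build_display(basic_condition("high", "neutral"), "N", 1, 5)
  fl <- high$items$identity[high$items$role == "flanker"]
  expect_true(all(fl %in% default_config()$display$high_load_letters))
  expect_false(any(fl %in% c("X", "N", "O")))
})

test_that("dilution cells set item counts and colors per design", {
  cfg <- default_config()
  ll <- build_display(condition_spec("ll", "low", "incompatible",
                                     dilution = "low"), "X", 0, 4, cfg)
  expect_equal(nrow(ll$items), 2)  # target + white distractor only
  dtr <- ll$items[ll$items$role == "distractor", ]
  expect_equal(c(dtr$r, dtr$g, dtr$b), cfg$display$color_white)

  lh <- build_display(condition_spec("lh", "low", "incompatible",
                                     dilution = "high"), "X", 0, 4, cfg)
  expect_equal(nrow(lh$items), 5)
  tgt <- lh$items[lh$items$role == "target", ]
  fls <- lh$items[lh$items$role == "flanker", ]
  # opposite colors in the high-dilution low-load cell
  expect_true(all(abs(fls$r - tgt$r) > 0.3))

  hh <- build_display(condition_spec("hh", "high", "incompatible",
                                     dilution = "high"), "X", 0, 4, cfg)
  tgt <- hh$items[hh$items$role == "target", ]
  fls <- hh$items[hh$items$role == "flanker", ]
  expect_true(all(fls$r == tgt$r & fls$g == tgt$g))  # same color
})

test_that("cued displays place the cue on the target (100% validity)", {
  d <- build_display(basic_condition("low", "incompatible", cued = TRUE),
                     "X", 3, 9)
  tgt <- d$items[d$items$role == "target", ]
  expect_equal(d$cue, c(tgt$x, tgt$y))
  expect_identical(d$task_region$kind, "point")
  expect_equal(d$task_region$n_locations, 1L)
})

test_that("rendering is deterministic and draws every glyph", {
  d <- build_display(basic_condition("low", "incompatible"), "X", 0, 11)
  img1 <- render_display(d)
  img2 <- render_display(d)
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(d$canvas[2], d$canvas[1], 3))
  # empty display renders the uniform background
  d0 <- d; d0$items <- d$items[0, ]
  img0 <- render_display(d0)
  expect_true(all(img0[, , 1] == d$background[1]))
  # the distractor glyph bounding box is strictly larger than the target's
  fp_t <- loadsim:::glyph_footprint(d$items[d$items$role == "target", ],
                                    d$canvas)
  fp_d <- loadsim:::glyph_footprint(d$items[d$items$role == "distractor", ],
                                    d$canvas)
  bb <- function(m) apply(which(m, arr.ind = TRUE), 2, function(v) diff(range(v)))
  expect_true(all(bb(fp_d) > bb(fp_t)))
})

test_that("item masks are disjoint, cover the glyphs, and order by size", {
  cfg <- default_config()
  d <- build_display(basic_condition("high", "incompatible"), "N", 4, 8, cfg)
  masks <- item_masks(d, cfg)
  expect_length(masks, nrow(d$items))
  tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_lte(max(tot), 1L)
  sizes <- vapply(masks, sum, numeric(1))
  expect_gt(sizes[["distractor"]], max(sizes[names(sizes) != "distractor"]))
  # background-only display has no mask pixels
  d0 <- d; d0$items <- d$items[0, ]
  expect_length(item_masks(d0, cfg), 0)
})

test_that("overlapping glyphs are reported, not merged", {
  cfg <- default_config()
  d <- build_display(basic_condition("low", "neutral"), "X", 0, 2, cfg)
  d$items$x <- rep(d$items$x[1], nrow(d$items))
  d$items$y <- rep(d$items$y[1], nrow(d$items))
  expect_error(item_masks(d, cfg), "overlap")
})

test_that("items are recoverable from render + masks (round trip)", {
  cfg <- default_config()
  d <- build_display(basic_condition("high", "incompatible"), "X", 2, 13, cfg)
  img <- render_display(d)
  masks <- item_masks(d, cfg)
  lit <- img[, , 1] > cfg$display$background[1] + 0.1
  for (i in seq_len(nrow(d$items))) {
    it <- d$items[i, ]
    m <- masks[[it$id]] & lit
    idx <- which(m, arr.ind = TRUE)             # (row, col) = (y+1, x+1)
    cent <- (apply(idx, 2, min) + apply(idx, 2, max)) / 2
    expect_lt(abs(cent[1] - 1 - it$y), 2)
    expect_lt(abs(cent[2] - 1 - it$x), 2)
    # identity recoverable: rendered patch matches its own glyph best
    scores <- vapply(glyph_set(), function(g) {
      fp <- loadsim:::glyph_footprint(
        tibble::tibble(identity = g, x = it$x, y = it$y, size = it$size),
        d$canvas)
      sum(fp & m) / sum(fp | m)
    }, numeric(1))
    expect_identical(names(which.max(scores)), it$identity)
  }
})

test_that("display YAML serialization round-trips", {
  cn <- basic_condition("high", "incompatible")
  d <- build_display(cn, "N", 5, 21)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_display(d, path)
  d2 <- read_display(path)
  expect_equal(d2$items$identity, d$items$identity)
  expect_equal(d2$items$x, d$items$x, tolerance = 1e-9)
  expect_equal(d2$task_region$n_locations, d$task_region$n_locations)
  expect_identical(render_display(d2), render_display(d))
})

test_that("PNG export writes a readable lossless raster", {
  d <- build_display(basic_condition("low", "compatible"), "X", 0, 2)
  path <- withr::local_tempfile(fileext = ".png")
  write_display_png(d, path)
  back <- png::readPNG(path)
  expect_equal(dim(back), dim(render_display(d)))
  expect_equal(max(abs(back - render_display(d))), 0, tolerance = 1 / 255)
})

test_that("the condition registry covers every cell of the four studies", {
  expect_length(experiment_conditions("basic_load"), 6)      # 2 loads x 3 compat
  expect_length(experiment_conditions("cueing"), 8)          # 2 x 2 x 2
  expect_length(experiment_conditions("central_distractor"), 8)
  expect_length(experiment_conditions("dilution"), 6)        # 3 cells x 2
  cues <- vapply(experiment_conditions("cueing"), `[[`, logical(1), "cued")
  expect_equal(sum(cues), 4)
  pos <- vapply(experiment_conditions("central_distractor"), `[[`,
                character(1), "distractor_position")
  expect_equal(sum(pos == "central"), 4)
  # every registered condition builds a valid display
  for (cn in experiment_conditions("dilution")) {
    expect_s3_class(build_display(cn, "X", 0, 1)$items, "tbl_df")
  }
})
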