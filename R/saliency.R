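# Bottom-up saliency: Koch-Ullman architecture in its standard center-surround
# formulation. Intensity, red-green and blue-yellow opponency, and oriented
# Gabor channels are computed on a Gaussian pyramid; across-scale differences
# are weighted by a peak-promoting normalization and summed into conspicuity
# maps, whose mean is the saliency map.

gaussian_kernel_5 <- function() {
  k <- c(1, 4, 6, 4, 1) / 16
  outer(k, k)
}

# One pyramid reduction: 5-tap binomial blur then 2x decimation. Levels too
# small for the blur kernel are decimated directly.
pyr_reduce <- function(m) {
  if (min(dim(m)) < 2) return(m)
  if (min(dim(m)) >= 5) {
    m <- EBImage::filter2(m, gaussian_kernel_5(), boundary = "replicate")
  }
  m[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

build_pyramid <- function(m, n_levels) {
  pyr <- vector("list", n_levels + 1)
  pyr[[1]] <- m
  for (l in seq_len(n_levels)) {
    pyr[[l + 1]] <- pyr_reduce(pyr[[l]])
  }
  pyr
}

resize_to <- function(m, nr, nc) {
  if (nrow(m) == nr && ncol(m) == nc) return(m)
  if (min(dim(m)) < 2) return(matrix(mean(m), nr, nc))
  EBImage::resize(m, w = nr, h = nc, filter = "bilinear")
}

# |center - surround| with the surround level upsampled to the center size.
center_surround <- function(pyr, c_lvl, s_lvl) {
  cm <- pyr[[c_lvl + 1]]
  sm <- resize_to(pyr[[s_lvl + 1]], nrow(cm), ncol(cm))
  abs(cm - sm)
}

# Oriented Gabor with an envelope elongated along the bar axis: extended
# straight strokes (letter diagonals/stems) respond much more strongly than
# the short tangent segments of curved glyphs, which carries the
# iso-orientation pop-out of a line singleton among rings.
gabor_kernel <- function(theta, size = 15, wavelength = 6,
                         sigma_perp = 2.5, sigma_along = 6) {
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, each = size), size, size)
  ys <- matrix(rep(-half:half, times = size), size, size)
  xr <- xs * cos(theta) + ys * sin(theta)   # across the bar (modulated)
  yr <- -xs * sin(theta) + ys * cos(theta)  # along the bar
  g <- exp(-(xr^2 / sigma_perp^2 + yr^2 / sigma_along^2) / 2) *
    cos(2 * pi * xr / wavelength)
  g - mean(g)                               # zero DC response
}

# Gaussian blur that degrades gracefully on maps smaller than the kernel
# (a very wide surround is then just the map mean).
blur_safe <- function(m, sigma) {
  ks <- 2 * ceiling(3 * sigma) + 1
  if (ks >= min(dim(m))) return(matrix(mean(m), nrow(m), ncol(m)))
  EBImage::gblur(m, sigma = sigma)
}

# Within-map spatial competition (iterative difference-of-Gaussians).
# Locations with similarly-responding neighbors suppress each other --
# iso-feature suppression: a ring of identical items damps itself within
# each feature map, while heterogeneous items, spread across different
# maps, escape. Applied per center-surround map before peak weighting.
compete_map <- function(m, n_iter = 2, c_ex = 0.5, c_in = 1.0) {
  mx <- max(m)
  if (mx <= 0) return(m)
  m <- m / mx
  s_ex <- max(0.8, 0.02 * ncol(m))
  s_in <- max(2, 0.25 * ncol(m))
  for (i in seq_len(n_iter)) {
    m <- pmax(m + c_ex * blur_safe(m, s_ex) - c_in * blur_safe(m, s_in), 0)
    top <- max(m)
    if (top > 0) m <- m / top
  }
  m * mx
}

# Peak-promoting normalization: scale to [0, 1], then weight by the squared
# gap between the global maximum and the mean of the other significant
# local maxima, so maps with one dominant peak contribute more than
# cluttered maps. Peaks are detected with a 5x5 non-max suppression and a
# significance threshold, so stroke-level micro-bumps do not dilute the
# competition.
normalize_map <- function(m, thresh = 0.06) {
  mx <- max(m)
  if (mx <= 1e-9) return(m * 0)   # flat map (numerical dust is not signal)
  m <- m / mx
  nms <- min(5, min(dim(m)))
  if (nms >= 3) {
    if (nms %% 2 == 0) nms <- nms - 1
    localmax <- EBImage::dilate(m, EBImage::makeBrush(nms, "box"))
    peaks <- m[m >= localmax - 1e-12 & m > thresh]
  } else {
    peaks <- m[m > thresh]
  }
  peaks <- peaks[peaks < 1 - 1e-9]
  mbar <- if (length(peaks)) mean(peaks) else 0
  m * (1 - mbar)^2
}

rgb_channels <- function(image) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  intensity <- (r + g + b) / 3
  # hue decoupled from intensity: normalize where intensity is appreciable
  scale <- pmax(intensity, max(intensity) / 10)
  nz <- intensity > max(intensity) / 10
  rn <- ifelse(nz, r / scale, 0)
  gn <- ifelse(nz, g / scale, 0)
  bn <- ifelse(nz, b / scale, 0)
  # half-rectified opponency: keeping R/G and B/Y poles as separate maps
  # lets the per-map peak competition promote a color singleton (a red item
  # among greens peaks alone in the R maps while the green items compete
  # with each other in the G maps), an iso-color suppression analogue
  R <- pmax(rn - (gn + bn) / 2, 0)
  G <- pmax(gn - (rn + bn) / 2, 0)
  B <- pmax(bn - (rn + gn) / 2, 0)
  Y <- pmax((rn + gn) / 2 - abs(rn - gn) / 2 - bn, 0)
  list(intensity = intensity, R = R, G = G, B = B, Y = Y)
}

#' Compute a bottom-up saliency map
#'
#' Runs the standard center-surround saliency pipeline on a rendered
#' display: a Gaussian pyramid of intensity, red-green and blue-yellow
#' opponency, and four oriented Gabor channels; across-scale differences for
#' center scales and surround offsets set in the config; peak-promoting
#' per-map normalization; channel conspicuity maps averaged into the final
#' map. The map is computed at reduced resolution, bilinearly upsampled to
#' the input size, and scaled to `[0, 1]` (a spatially uniform input yields
#' an identically zero map).
#'
#' @param image RGB array `height x width x 3` (values in `[0, 1]`), e.g.
#'   from [render_display()]; a matrix is treated as grayscale.
#' @param config Model configuration, see [default_config()].
#' @return A `saliency_map` object: list with `values` (matrix at input
#'   resolution), `map_level`, and `normalized`.
#' @export
compute_saliency_map <- function(image, config = default_config()) {
  if (is.matrix(image)) {
    image <- array(rep(image, 3), dim = c(dim(image), 3))
  }
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("image must be a height x width x 3 array", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  sc <- config$saliency
  if (min(h, w) < 64) stop("image must be at least 64 x 64", call. = FALSE)

  ch <- rgb_channels(image)
  pyr_i <- build_pyramid(ch$intensity, sc$n_levels)
  pyr_col <- lapply(ch[c("R", "G", "B", "Y")], build_pyramid, sc$n_levels)

  # orientation energy extracted at full resolution (letter strokes are only
  # a few px wide) and then pyramided, so coarse levels pool fine energy
  # instead of blurring it away
  thetas <- (seq_len(sc$n_orientations) - 1) * pi / sc$n_orientations
  pyr_o <- lapply(thetas, function(th) {
    kern <- gabor_kernel(th, size = sc$gabor_size)
    energy <- abs(EBImage::filter2(ch$intensity, kern, boundary = "replicate"))
    build_pyramid(energy, sc$n_levels)
  })

  map_dim <- dim(pyr_i[[sc$map_level + 1]])
  at_map <- function(m) resize_to(m, map_dim[1], map_dim[2])
  pairs <- expand.grid(c_lvl = sc$center_scales, delta = sc$surround_deltas)

  sum_pairs <- function(pyr) {
    total <- matrix(0, map_dim[1], map_dim[2])
    for (i in seq_len(nrow(pairs))) {
      cs <- center_surround(pyr, pairs$c_lvl[i], pairs$c_lvl[i] + pairs$delta[i])
      cs <- compete_map(cs, sc$compete_iter)
      total <- total + at_map(normalize_map(cs, sc$local_max_thresh))
    }
    total
  }

  consp_i <- normalize_map(sum_pairs(pyr_i), sc$local_max_thresh)
  # color axes compete winner-take-all: the strongest opponent pole at each
  # location carries the color conspicuity
  consp_c <- Reduce(pmax, lapply(pyr_col, function(p) {
    normalize_map(sum_pairs(p), sc$local_max_thresh)
  }))
  consp_c <- normalize_map(consp_c, sc$local_max_thresh)
  consp_o <- Reduce(`+`, lapply(pyr_o, function(p) {
    normalize_map(sum_pairs(p), sc$local_max_thresh)
  }))
  consp_o <- normalize_map(consp_o, sc$local_max_thresh)

  s <- (consp_i + consp_c + consp_o) / 3
  if (max(s) <= 1e-9) s <- s * 0 else s <- s / max(s)
  # compressive response nonlinearity (strictly monotone, order-preserving):
  # a semisaturation constant k compresses the top of the range and expands
  # mid-range contrasts, like neural contrast response functions
  if (sc$semisat > 0) {
    k2 <- sc$semisat^2
    s <- (s^2 / (s^2 + k2)) * (1 + k2)
  }
  values <- resize_to(s, h, w)
  if (max(values) > 0) values <- values / max(values)  # unit max at full size
  structure(
    list(values = values, map_level = sc$map_level,
         normalized = TRUE),
    class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat("<saliency_map>", nrow(x$values), "x", ncol(x$values),
      " max:", signif(max(x$values), 3), "\n")
  invisible(x)
}

#' Per-stimulus saliency values
#'
#' Reduces a saliency map to one scalar per item: the maximum map value
#' within the item's mask (robust to thin glyph strokes).
#'
#' @param map A `saliency_map` from [compute_saliency_map()].
#' @param masks Named list of logical masks from [item_masks()] for the same
#'   display.
#' @param items Optional item tibble (`display$items`) to carry identity and
#'   role into the result.
#' @return A tibble with columns `id`, `s`, and, when `items` is supplied,
#'   `identity` and `role`.
#' @export
stimulus_saliency <- function(map, masks, items = NULL) {
  stopifnot(inherits(map, "saliency_map"))
  if (any(!vapply(masks, any, logical(1)))) {
    stop("empty mask", call. = FALSE)
  }
  s <- vapply(masks, function(m) max(map$values[m]), numeric(1))
  out <- tibble::tibble(id = names(masks), s = unname(s))
  if (!is.null(items)) {
    out <- dplyr::left_join(
      out, dplyr::select(items, dplyr::all_of(c("id", "identity", "role"))),
      by = "id")
    out <- dplyr::relocate(out, dplyr::all_of(c("id", "identity", "role")))
  }
  out
}

#' Export a saliency map as a lossless grayscale raster
#'
#' @param map A `saliency_map`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_saliency_png <- function(map, path) {
  png::writePNG(map$values, path)
  invisible(path)
}
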