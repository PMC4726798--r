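# Bundled 5x7 monospaced bitmap font. Defining glyphs in source keeps
# rendering bit-reproducible across platforms (no system font dependency).

.font5x7 <- local({
  g <- function(...) {
    rows <- c(...)
    m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
    storage.mode(m) <- "integer"
    m
  }
  list(
    X = g("10001", "10001", "01010", "00100", "01010", "10001", "10001"),
    N = g("10001", "11001", "11001", "10101", "10011", "10011", "10001"),
    O = g("01110", "10001", "10001", "10001", "10001", "10001", "01110"),
    P = g("11110", "10001", "10001", "11110", "10000", "10000", "10000"),
    K = g("10001", "10010", "10100", "11000", "10100", "10010", "10001"),
    M = g("10001", "11011", "10101", "10101", "10001", "10001", "10001"),
    V = g("10001", "10001", "10001", "10001", "01010", "01010", "00100"),
    W = g("10001", "10001", "10001", "10101", "10101", "11011", "10001"),
    Z = g("11111", "00001", "00010", "00100", "01000", "10000", "11111"),
    H = g("10001", "10001", "10001", "11111", "10001", "10001", "10001"),
    C = g("01110", "10001", "10000", "10000", "10000", "10001", "01110"),
    S = g("01111", "10000", "10000", "01110", "00001", "00001", "11110"),
    T = g("11111", "00100", "00100", "00100", "00100", "00100", "00100")
  )
})

#' Letters with a bundled glyph
#'
#' @return Character vector of identities the renderer can draw.
#' @export
glyph_set <- function() names(.font5x7)

# Binary glyph matrix scaled to the requested pixel height (nearest neighbor;
# width preserves the 5:7 aspect).
glyph_bitmap <- function(identity, height) {
  base <- .font5x7[[identity]]
  if (is.null(base)) {
    stop("no glyph available for identity '", identity, "'", call. = FALSE)
  }
  h <- as.integer(round(height))
  w <- max(1L, as.integer(round(h * ncol(base) / nrow(base))))
  ri <- pmin(nrow(base), pmax(1L, ceiling(seq_len(h) / h * nrow(base))))
  ci <- pmin(ncol(base), pmax(1L, ceiling(seq_len(w) / w * ncol(base))))
  base[ri, ci, drop = FALSE]
}
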