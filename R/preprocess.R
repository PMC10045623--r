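#' @keywords internal
assert_gray <- function(img) {
  if (!is.matrix(img) || length(img) == 0L)
    stop("image must be a non-empty numeric matrix")
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255))
    stop("image intensities must lie in [0, 255]")
  invisible(img)
}

#' Conditional-mean impulse noise filter
#'
#' Replaces every extreme pixel (intensity exactly 0 or 255, the
#' salt-and-pepper values) by the rounded mean of its window
#' neighborhood, excluding neighbors that are themselves extreme. If the
#' whole window is extreme the plain full-window mean is used instead.
#' Non-extreme pixels pass through untouched, so the filter is a
#' conditional mean, not a blur.
#'
#' @param img Integer matrix with values in `[0, 255]`.
#' @param window Odd window side length, >= 3.
#' @return The filtered image (integer matrix, same shape).
#' @export
remove_impulse_noise <- function(img, window = 3L) {
  assert_gray(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3")
  ext <- img == 0 | img == 255
  if (!any(ext)) return(img)
  out <- img
  h <- nrow(img); w <- ncol(img); r <- window %/% 2L
  idx <- which(ext, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    rows <- max(1L, i - r):min(h, i + r)
    cols <- max(1L, j - r):min(w, j + r)
    vals <- img[rows, cols]
    good <- vals[vals != 0 & vals != 255]
    out[i, j] <- if (length(good)) round(mean(good)) else round(mean(vals))
  }
  storage.mode(out) <- "integer"
  out
}

#' Tiled adaptive histogram equalization
#'
#' Classical rank/CDF equalization applied per tile with bilinear
#' blending of the tile mappings. Within a tile an intensity v maps to
#' `floor(cdf(v) / n_tile * 255)` where `cdf(v)` counts tile pixels at or
#' below v; a tile holding a single unique value maps to itself (plain
#' equalization would jump a flat region to white). Pixel values are then
#' bilinearly interpolated between the mapped values of the four
#' surrounding tile centers, which removes tile-boundary seams. There is
#' no clip limit by default; `clip_limit` (a multiple of the uniform bin
#' count) enables contrast limiting, redistributing the excess uniformly.
#'
#' @param img Integer matrix with values in `[0, 255]`, at least one
#'   tile in each dimension.
#' @param tiles Integer pair `(rows, cols)` of the tile grid.
#' @param clip_limit NULL (off) or a positive multiple of the mean
#'   histogram count at which each tile histogram is clipped.
#' @return The equalized image (integer matrix, same shape, values in
#'   `[0, 255]`; per-tile mappings are monotone in the input intensity).
#' @export
adaptive_hist_eq <- function(img, tiles = c(8L, 8L), clip_limit = NULL) {
  assert_gray(img)
  tr <- as.integer(tiles[1L]); tc <- as.integer(tiles[2L])
  h <- nrow(img); w <- ncol(img)
  if (tr < 1L || tc < 1L) stop("`tiles` must be positive")
  if (tr > h || tc > w) stop("tiles larger than image")

  rb <- floor(seq(0L, h, length.out = tr + 1L))  # tile row boundaries
  cb <- floor(seq(0L, w, length.out = tc + 1L))
  luts <- matrix(0, nrow = tr * tc, ncol = 256L)
  cy <- numeric(tr); cx <- numeric(tc)
  for (i in seq_len(tr)) cy[i] <- (rb[i] + 1L + rb[i + 1L]) / 2
  for (j in seq_len(tc)) cx[j] <- (cb[j] + 1L + cb[j + 1L]) / 2

  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      tile <- img[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      id <- (i - 1L) * tc + j
      counts <- tabulate(as.integer(tile) + 1L, nbins = 256L)
      if (sum(counts > 0L) <= 1L) {        # constant tile: identity map
        luts[id, ] <- 0:255
        next
      }
      if (!is.null(clip_limit)) {
        cap <- clip_limit * length(tile) / 256
        excess <- sum(pmax(counts - cap, 0))
        counts <- pmin(counts, cap) + excess / 256
      }
      luts[id, ] <- floor(cumsum(counts) / sum(counts) * 255)
    }
  }

  # bilinear blending between tile-center mappings
  yy <- seq_len(h); xx <- seq_len(w)
  i0 <- pmin(pmax(findInterval(yy, cy), 1L), max(tr - 1L, 1L))
  j0 <- pmin(pmax(findInterval(xx, cx), 1L), max(tc - 1L, 1L))
  i1 <- pmin(i0 + 1L, tr); j1 <- pmin(j0 + 1L, tc)
  wy <- if (tr == 1L) rep(0, h) else
    pmin(pmax((yy - cy[i0]) / (cy[i1] - cy[i0] + (i1 == i0)), 0), 1)
  wx <- if (tc == 1L) rep(0, w) else
    pmin(pmax((xx - cx[j0]) / (cx[j1] - cx[j0] + (j1 == j0)), 0), 1)

  v <- as.integer(img) + 1L                 # column index into the LUTs
  I0 <- matrix(i0, h, w); I1 <- matrix(i1, h, w)
  J0 <- matrix(j0, h, w, byrow = TRUE); J1 <- matrix(j1, h, w, byrow = TRUE)
  WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)
  tid <- function(I, J) (I - 1L) * tc + J
  g00 <- luts[cbind(as.vector(tid(I0, J0)), v)]
  g01 <- luts[cbind(as.vector(tid(I0, J1)), v)]
  g10 <- luts[cbind(as.vector(tid(I1, J0)), v)]
  g11 <- luts[cbind(as.vector(tid(I1, J1)), v)]
  out <- (1 - WY) * (1 - WX) * g00 + (1 - WY) * WX * g01 +
    WY * (1 - WX) * g10 + WY * WX * g11
  out <- matrix(pmin(pmax(round(out), 0), 255), h, w)
  storage.mode(out) <- "integer"
  out
}

#' Preprocess one CT image
#'
#' The standard two-step cleanup: impulse-noise removal followed by
#' tiled adaptive histogram equalization.
#'
#' @inheritParams remove_impulse_noise
#' @inheritParams adaptive_hist_eq
#' @return The preprocessed image.
#' @export
preprocess_image <- function(img, window = 3L, tiles = c(8L, 8L),
                             clip_limit = NULL) {
  adaptive_hist_eq(remove_impulse_noise(img, window), tiles, clip_limit)
}
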