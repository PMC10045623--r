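#' Settings for the synthetic lung-CT phantom generator
#'
#' Emulates a 4-class chest-CT dataset (three carcinoma texture classes
#' and a normal class) at desk scale: each image is a smooth lung-like
#' low-frequency background in `[40, 180]` with class-specific bright
#' elliptical blobs added; the normal class has none. The blobs are a
#' stand-in for the lesion appearance that separates the classes, not
#' for nodule radiology. A fraction `noise_p` of the pixels is then hit
#' by salt-and-pepper impulses so the preprocessing stage has something
#' to remove.
#'
#' @param n_per_class Images per class (default 100, 400 in total).
#' @param size Image size `c(height, width)`, each >= 16.
#' @param seed Integer seed; generation is pure given the seed.
#' @param noise_p Impulse-noise pixel fraction in `[0, 1)`.
#' @param class_params Optional list (one entry per class) with fields
#'   `blobs` (count), `radius` (`c(min, max)` semi-axis in pixels) and
#'   `amplitude` (added intensity). The defaults give the classes a
#'   clear lesion-burden/size gradient: many medium blobs, two large
#'   blobs, none, and very many tiny blobs respectively, so the global
#'   texture features separate them.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 100L, size = c(64L, 64L), seed = 1L,
                         noise_p = 0.02, class_params = NULL) {
  size <- as.integer(size)
  if (any(size < 16L)) stop("`size` must be at least 16 in each dimension")
  if (!is.finite(noise_p) || noise_p < 0 || noise_p >= 1)
    stop("`noise_p` must lie in [0, 1)")
  classes <- c("adenocarcinoma", "large_cell_carcinoma",
               "normal", "squamous_cell_carcinoma")
  if (is.null(class_params)) {
    class_params <- list(
      adenocarcinoma          = list(blobs = 25L, radius = c(3, 4),   amplitude = 100),
      large_cell_carcinoma    = list(blobs = 4L,  radius = c(14, 18), amplitude = 120),
      normal                  = list(blobs = 0L,  radius = c(0, 0),   amplitude = 0),
      squamous_cell_carcinoma = list(blobs = 80L, radius = c(1, 1.8), amplitude = 100))
  }
  if (length(class_params) != 4L) stop("exactly four classes are modelled")
  structure(list(n_per_class = as.integer(n_per_class), size = size,
                 seed = as.integer(seed), noise_p = noise_p,
                 classes = classes, class_params = class_params),
            class = "synth_config")
}

# bilinear upsampling of a coarse grid to (h, w); the low-frequency field
upsample_bilinear <- function(g, h, w) {
  gy <- seq(1, nrow(g), length.out = h)
  gx <- seq(1, ncol(g), length.out = w)
  y0 <- pmin(floor(gy), nrow(g) - 1L); x0 <- pmin(floor(gx), ncol(g) - 1L)
  wy <- gy - y0; wx <- gx - x0
  a <- g[y0, x0, drop = FALSE]; b <- g[y0, x0 + 1L, drop = FALSE]
  c2 <- g[y0 + 1L, x0, drop = FALSE]; d <- g[y0 + 1L, x0 + 1L, drop = FALSE]
  WY <- matrix(wy, h, w); WX <- matrix(wx, h, w, byrow = TRUE)
  (1 - WY) * (1 - WX) * a + (1 - WY) * WX * b +
    WY * (1 - WX) * c2 + WY * WX * d
}

# one phantom: low-frequency background plus rotated Gaussian ellipses
phantom_image <- function(size, params) {
  h <- size[1]; w <- size[2]
  bg <- upsample_bilinear(matrix(stats::runif(64), 8L, 8L), h, w)
  img <- 40 + bg * 140
  if (params$blobs > 0L) {
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    for (b in seq_len(params$blobs)) {
      cy <- stats::runif(1, 0.15 * h, 0.85 * h)
      cx <- stats::runif(1, 0.15 * w, 0.85 * w)
      ra <- stats::runif(1, params$radius[1], params$radius[2])
      rb <- ra * stats::runif(1, 0.6, 1)
      th <- stats::runif(1, 0, pi)
      u <- (cos(th) * (xx - cx) + sin(th) * (yy - cy)) / ra
      v <- (-sin(th) * (xx - cx) + cos(th) * (yy - cy)) / rb
      img <- img + params$amplitude * exp(-(u^2 + v^2))
    }
  }
  out <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), h, w)
  out
}

#' Corrupt an image with salt-and-pepper impulses
#'
#' Each pixel is independently replaced, with probability `p`, by 0 or
#' 255 (equal odds).
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param p Impulse probability in `[0, 1)`.
#' @param seed Optional seed; when NULL the current RNG stream is used.
#' @return The corrupted image.
#' @export
add_impulse_noise <- function(img, p, seed = NULL) {
  assert_gray(img)
  if (!is.finite(p) || p < 0 || p >= 1) stop("`p` must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (p == 0) return(img)
  hit <- stats::runif(length(img)) < p
  vals <- sample(c(0L, 255L), sum(hit), replace = TRUE)
  out <- img
  out[hit] <- vals
  out
}

#' Generate the synthetic 4-class phantom dataset
#'
#' @param config A [synth_config()].
#' @return Object of class `phantom_dataset`: `images` (list of integer
#'   matrices), `labels` (integers 0-3, in class order), `classes`
#'   (names) and the config echo. Deterministic given `config$seed`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  images <- list(); labels <- integer(0)
  for (cl in seq_along(config$classes)) {
    par <- config$class_params[[cl]]
    for (i in seq_len(config$n_per_class)) {
      img <- phantom_image(config$size, par)
      if (config$noise_p > 0) img <- add_impulse_noise(img, config$noise_p)
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl - 1L)
    }
  }
  structure(list(images = images, labels = labels,
                 classes = config$classes, config = config),
            class = "phantom_dataset")
}

#' Write a phantom dataset to disk
#'
#' Lays out `root/<class>/img_####.pgm` (plain-text PGM) plus a
#' `manifest.csv` with columns `path,label,seed`.
#'
#' @param ds A `phantom_dataset`.
#' @param root Output directory (created if missing).
#' @param provenance Optional named list added to the manifest header.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, root, provenance = NULL) {
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  counters <- stats::setNames(integer(length(ds$classes)), ds$classes)
  paths <- character(length(ds$images))
  for (i in seq_along(ds$images)) {
    cl <- ds$classes[ds$labels[i] + 1L]
    dir.create(file.path(root, cl), showWarnings = FALSE)
    counters[cl] <- counters[cl] + 1L
    paths[i] <- file.path(cl, sprintf("img_%04d.pgm", counters[cl]))
    write_pgm(ds$images[[i]], file.path(root, paths[i]),
              comment = paste("seed", ds$config$seed))
  }
  manifest <- data.frame(path = paths, label = ds$labels,
                         seed = ds$config$seed)
  mf <- file.path(root, "manifest.csv")
  con <- file(mf, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", paste(names(provenance), unlist(provenance),
                                  sep = "=", collapse = " ")), con)
  utils::write.csv(manifest, con, row.names = FALSE)
  invisible(mf)
}

#' Read a class-per-folder image dataset from disk
#'
#' Expects `root/<class>/*.pgm`; class order is alphabetical unless a
#' `manifest.csv` is present, in which case the manifest order is used.
#'
#' @param root Dataset directory.
#' @return A `phantom_dataset`-shaped list (`images`, `labels`,
#'   `classes`).
#' @export
read_dataset <- function(root) {
  if (!dir.exists(root)) stop(sprintf("dataset directory '%s' not found", root))
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0L) stop("no class folders found")
  images <- list(); labels <- integer(0)
  for (cl in seq_along(classes)) {
    files <- sort(list.files(file.path(root, classes[cl]),
                             pattern = "\\.pgm$", full.names = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- read_pgm(f)
      labels <- c(labels, cl - 1L)
    }
  }
  structure(list(images = images, labels = labels, classes = classes),
            class = "phantom_dataset")
}
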