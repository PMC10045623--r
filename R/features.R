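#' Feature-extraction settings
#'
#' Standard Haralick-style texture settings: 8 quantized gray levels,
#' offset distance 1 at the four canonical angles, symmetric
#' accumulation, features averaged across angles; a single-level
#' orthonormal Haar wavelet; 256 histogram bins.
#'
#' @param glcm_levels Number of quantized gray levels L >= 2.
#' @param glcm_distance Co-occurrence offset distance >= 1.
#' @param glcm_angles Angles in degrees, subset of \{0, 45, 90, 135\}.
#' @param histogram_bins Number of intensity bins (8-bit images: 256).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(glcm_levels = 8L, glcm_distance = 1L,
                           glcm_angles = c(0, 45, 90, 135),
                           histogram_bins = 256L) {
  glcm_levels <- as.integer(glcm_levels)
  glcm_distance <- as.integer(glcm_distance)
  if (glcm_levels < 2L) stop("`glcm_levels` must be >= 2")
  if (glcm_distance < 1L) stop("`glcm_distance` must be >= 1")
  if (!all(glcm_angles %in% c(0, 45, 90, 135)))
    stop("`glcm_angles` must be a subset of {0, 45, 90, 135}")
  structure(list(glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                 glcm_angles = glcm_angles, histogram_bins = histogram_bins),
            class = "feature_config")
}

#' Quantize an 8-bit image to L gray levels
#'
#' Intensity v maps to `floor(v * L / 256)`, giving levels 0 .. L-1.
#'
#' @param img Integer matrix with values in `[0, 255]`.
#' @param levels Number of levels L >= 2.
#' @return Integer matrix of levels in `[0, L - 1]`.
#' @export
quantize_image <- function(img, levels) {
  assert_gray(img)
  levels <- as.integer(levels)
  if (levels < 2L) stop("`levels` must be >= 2")
  out <- matrix(as.integer(floor(as.numeric(img) * levels / 256)),
                nrow(img), ncol(img))
  out
}

# displacement (drow, dcol) for a GLCM angle in degrees
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle"))
}

#' Gray-level co-occurrence matrices
#'
#' Counts co-occurring level pairs at each configured angle/distance
#' offset, accumulating both orderings (symmetric GLCM), and normalizes
#' each matrix to probabilities. One L-by-L matrix per angle.
#'
#' @param lv Integer matrix of quantized levels in `[0, L - 1]`
#'   (see [quantize_image()]).
#' @param config A [feature_config()].
#' @return Object of class `glcm_set`: a list of normalized matrices
#'   (one per angle) with attribute `levels`.
#' @export
compute_glcm <- function(lv, config = feature_config()) {
  if (!is.matrix(lv) || length(lv) == 0L) stop("level image must be a matrix")
  L <- config$glcm_levels
  if (any(lv < 0L) || any(lv >= L)) stop("level image holds values outside [0, L-1]")
  d <- config$glcm_distance
  mats <- lapply(config$glcm_angles, function(ang) {
    off <- glcm_offset(ang, d)
    dy <- off[1L]; dx <- off[2L]
    h <- nrow(lv); w <- ncol(lv)
    r1 <- max(1L, 1L - dy); r2 <- min(h, h - dy)
    c1 <- max(1L, 1L - dx); c2 <- min(w, w - dx)
    if (r1 > r2 || c1 > c2)
      stop("image smaller than the co-occurrence offset")
    a <- lv[r1:r2, c1:c2, drop = FALSE]
    b <- lv[(r1 + dy):(r2 + dy), (c1 + dx):(c2 + dx), drop = FALSE]
    cnt <- tabulate(as.integer(a) * L + as.integer(b) + 1L, nbins = L * L)
    m <- matrix(cnt, L, L, byrow = TRUE)   # [i+1, j+1] = count of (i -> j)
    m <- m + t(m)                          # symmetric accumulation
    m / sum(m)
  })
  structure(mats, class = "glcm_set", levels = L)
}

# the five Haralick statistics of a single normalized GLCM
glcm_stats_one <- function(p) {
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0))
    stop("GLCM is not a normalized probability matrix")
  L <- nrow(p)
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  mi <- sum(i * p); mj <- sum(j * p)
  vi <- sum((i - mi)^2 * p); vj <- sum((j - mj)^2 * p)
  contrast <- sum(p * (i - j)^2)
  correlation <- if (vi <= 0 || vj <= 0) 1 else
    sum(p * (i - mi) * (j - mj)) / sqrt(vi * vj)
  homogeneity <- sum(p / (1 + (i - j)^2))
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))           # 0 log 0 taken as 0
  energy <- sum(p^2)
  c(contrast = contrast, correlation = correlation,
    homogeneity = homogeneity, entropy = entropy, energy = energy)
}

#' Haralick texture features from a GLCM set
#'
#' Per angle: contrast \eqn{\sum p (i-j)^2}; correlation
#' \eqn{\sum p (i-\mu_i)(j-\mu_j) / (\sigma_i \sigma_j)} (a zero-variance
#' matrix is taken as perfectly correlated, value 1); homogeneity
#' \eqn{\sum p / (1 + (i-j)^2)}; entropy \eqn{-\sum p \log_2 p}; energy
#' (angular second moment) \eqn{\sum p^2}. The five statistics are then
#' averaged over the angles.
#'
#' @param glcms A `glcm_set` from [compute_glcm()].
#' @return Named numeric vector `contrast, correlation, homogeneity,
#'   entropy, energy`.
#' @export
glcm_features <- function(glcms) {
  if (!inherits(glcms, "glcm_set")) stop("`glcms` must come from compute_glcm()")
  per_angle <- vapply(glcms, glcm_stats_one, numeric(5))
  rowMeans(per_angle)
}

# single-level paired Haar analysis along matrix columns (horizontal axis)
haar_cols <- function(m) {
  o <- m[, seq(1L, ncol(m) - 1L, by = 2L), drop = FALSE]
  e <- m[, seq(2L, ncol(m), by = 2L), drop = FALSE]
  list(a = (o + e) / sqrt(2), d = (o - e) / sqrt(2))
}

#' Single-level 2-D Haar wavelet sub-band features
#'
#' Applies the orthonormal 2-tap Haar analysis along columns then rows
#' (odd extents are first padded by edge replication) and summarizes each
#' sub-band by the mean absolute coefficient. LL is the coarse
#' approximation, LH responds to variation along the horizontal axis,
#' HL along the vertical axis and HH to diagonal detail.
#'
#' @param img Integer matrix with values in `[0, 255]`.
#' @return Named numeric vector `wav_LL, wav_LH, wav_HL, wav_HH`.
#' @export
dwt_subband_features <- function(img) {
  b <- haar_subbands(img)
  c(wav_LL = mean(abs(b$LL)), wav_LH = mean(abs(b$LH)),
    wav_HL = mean(abs(b$HL)), wav_HH = mean(abs(b$HH)))
}

#' Single-level 2-D Haar sub-bands
#'
#' @inheritParams dwt_subband_features
#' @return List of the four coefficient matrices `LL, LH, HL, HH`.
#' @export
haar_subbands <- function(img) {
  assert_gray(img)
  m <- img
  if (ncol(m) %% 2L == 1L) m <- cbind(m, m[, ncol(m)])  # edge replication
  if (nrow(m) %% 2L == 1L) m <- rbind(m, m[nrow(m), ])
  hx <- haar_cols(m)                        # horizontal split
  lo <- haar_cols(t(hx$a)); hi <- haar_cols(t(hx$d))  # vertical split
  list(LL = t(lo$a), HL = t(lo$d), LH = t(hi$a), HH = t(hi$d))
}

#' Inverse of [haar_subbands()]
#'
#' Reconstructs the (possibly edge-padded) image from its four
#' sub-bands; used by the round-trip tests.
#'
#' @param bands List `LL, LH, HL, HH` as returned by [haar_subbands()].
#' @return Numeric matrix.
#' @export
haar_reconstruct <- function(bands) {
  inv_cols <- function(a, d) {
    o <- (a + d) / sqrt(2); e <- (a - d) / sqrt(2)
    m <- matrix(0, nrow(a), 2L * ncol(a))
    m[, seq(1L, ncol(m) - 1L, by = 2L)] <- o
    m[, seq(2L, ncol(m), by = 2L)] <- e
    m
  }
  la <- t(inv_cols(t(bands$LL), t(bands$HL)))
  ha <- t(inv_cols(t(bands$LH), t(bands$HH)))
  inv_cols(la, ha)
}

#' First-order histogram statistics
#'
#' Sample mean, population variance m2, standard deviation, skewness
#' \eqn{m_3 / m_2^{3/2}} and excess (Fisher) kurtosis
#' \eqn{m_4 / m_2^2 - 3} of the pixel intensities, so a Gaussian image
#' reads kurtosis 0. A constant image returns skewness = kurtosis = 0 by
#' convention.
#'
#' @param img Integer matrix with values in `[0, 255]`.
#' @return Named numeric vector `hist_mean, hist_variance, hist_sd,
#'   hist_skewness, hist_kurtosis`.
#' @export
histogram_stats <- function(img) {
  assert_gray(img)
  x <- as.numeric(img)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 <= 0) {
    return(c(hist_mean = mu, hist_variance = 0, hist_sd = 0,
             hist_skewness = 0, hist_kurtosis = 0))
  }
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  c(hist_mean = mu, hist_variance = m2, hist_sd = sqrt(m2),
    hist_skewness = m3 / m2^1.5, hist_kurtosis = m4 / m2^2 - 3)
}

#' The 14-value image feature vector
#'
#' Deterministic concatenation of the four Haar sub-band means, the five
#' Haralick GLCM features and the five first-order histogram statistics,
#' in that fixed order.
#'
#' @param img Integer matrix with values in `[0, 255]` (normally already
#'   preprocessed).
#' @param config A [feature_config()].
#' @return Named numeric vector of length 14.
#' @export
extract_feature_vector <- function(img, config = feature_config()) {
  wav <- dwt_subband_features(img)
  tex <- glcm_features(compute_glcm(quantize_image(img, config$glcm_levels),
                                    config))
  names(tex) <- paste0("glcm_", names(tex))
  hst <- histogram_stats(img)
  c(wav, tex, hst)
}

#' Feature names in canonical order
#' @return Character vector of length 14.
#' @export
feature_names <- function() {
  c("wav_LL", "wav_LH", "wav_HL", "wav_HH",
    "glcm_contrast", "glcm_correlation", "glcm_homogeneity",
    "glcm_entropy", "glcm_energy",
    "hist_mean", "hist_variance", "hist_sd",
    "hist_skewness", "hist_kurtosis")
}

#' Batch feature extraction
#'
#' @param images List of gray images.
#' @param labels Vector of labels, one per image.
#' @param paths Optional character vector of source paths for the table.
#' @param config A [feature_config()].
#' @return A data.frame with columns `path`, `label` and the 14 features.
#' @export
extract_features_batch <- function(images, labels, paths = NULL,
                                   config = feature_config()) {
  stopifnot(length(images) == length(labels))
  if (is.null(paths)) paths <- sprintf("img_%04d", seq_along(images))
  feats <- t(vapply(images, extract_feature_vector, numeric(14),
                    config = config))
  out <- data.frame(path = paths, label = labels, feats,
                    stringsAsFactors = FALSE)
  names(out) <- c("path", "label", feature_names())
  out
}

#' Write / read a feature table CSV
#'
#' The file carries a `#`-prefixed provenance header line (config hash
#' and seed) followed by a standard CSV with header
#' `path,label,wav_LL,...,hist_kurtosis`.
#'
#' @param df Feature data.frame from [extract_features_batch()].
#' @param path Output file.
#' @param provenance Optional named list echoed into the header line.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", paste(names(provenance), unlist(provenance),
                                  sep = "=", collapse = " ")), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
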