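test_that("quantization maps 8-bit intensities onto L levels", {
  expect_identical(quantize_image(matrix(255L, 1, 1), 8)[1, 1], 7L)
  expect_identical(quantize_image(matrix(0L, 1, 1), 8)[1, 1], 0L)
  ramp <- matrix(as.integer(0:255), 16, 16)
  lv <- quantize_image(ramp, 8)
  expect_equal(as.vector(table(lv)), rep(32L, 8))
  expect_error(quantize_image(ramp, 1), ">= 2")
})

test_that("GLCM construction matches hand enumeration and normalizes", {
  cfgh <- feature_config(glcm_levels = 2, glcm_angles = 0)
  g <- compute_glcm(matrix(c(0L, 1L, 0L, 1L), 2, 2), cfgh)
  # rows of the image are (0,0) and (1,1): two horizontal pairs, both ways
  expect_equal(g[[1]], matrix(c(0.5, 0, 0, 0.5), 2, 2))

  flat <- matrix(0L, 4, 4)
  gf <- compute_glcm(flat, cfgh)
  expect_equal(gf[[1]][1, 1], 1)

  set.seed(7)
  for (rep in 1:10) {
    h <- sample(2:8, 1); w <- sample(2:8, 1)
    lv <- matrix(sample(0:7, h * w, TRUE), h, w)
    gs <- compute_glcm(lv, feature_config())
    for (ai in seq_along(gs)) {
      expect_equal(sum(gs[[ai]]), 1, tolerance = 1e-12)
      expect_equal(gs[[ai]], t(gs[[ai]]))
    }
  }
  expect_error(compute_glcm(matrix(0L, 1, 1), feature_config()),
               "smaller than")
})

test_that("texture features match the double-loop oracle", {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  set.seed(13)
  for (rep in 1:10) {
    lv <- matrix(sample(0:7, 49, TRUE), 7, 7)
    gs <- compute_glcm(lv, feature_config())
    want <- rowMeans(vapply(names(offs), function(a) {
      p <- oracle_glcm(lv, 8, offs[[a]][1], offs[[a]][2])
      oracle_glcm_feats(p)
    }, numeric(5)))
    expect_equal(glcm_features(gs), want, tolerance = 1e-12)
  }
})

test_that("degenerate and tiny GLCMs give their closed-form features", {
  flat <- compute_glcm(matrix(3L, 4, 4), feature_config())
  f <- glcm_features(flat)
  expect_equal(unname(f), c(0, 1, 1, 0, 1))   # contrast cor hom ent energy

  cfgh <- feature_config(glcm_levels = 2, glcm_angles = 0)
  g2 <- compute_glcm(matrix(c(0L, 0L, 1L, 1L), 2, 2), cfgh)
  expect_equal(glcm_features(g2)[["contrast"]], 1)  # every pair differs by 1

  set.seed(17)
  lv <- matrix(sample(0:7, 64, TRUE), 8, 8)
  f <- glcm_features(compute_glcm(lv, feature_config()))
  expect_lte(f[["energy"]], 1)
  expect_gt(f[["energy"]], 0)
  expect_lte(f[["entropy"]], 2 * log2(8))
  expect_gte(f[["entropy"]], 0)

  bad <- structure(list(matrix(0.3, 2, 2)), class = "glcm_set", levels = 2)
  expect_error(glcm_features(bad), "normalized")
})

test_that("Haar sub-bands match the transform-matrix oracle and invert", {
  set.seed(23)
  for (n in c(4, 8, 16)) {
    img <- random_gray(n, n, seed = n)
    got <- haar_subbands(img)
    want <- oracle_haar_subbands(img)
    for (b in c("LL", "LH", "HL", "HH"))
      expect_equal(got[[b]], want[[b]], tolerance = 1e-9,
                   ignore_attr = TRUE)
    expect_equal(haar_reconstruct(got), img, tolerance = 1e-9,
                 ignore_attr = TRUE)
    # Parseval: orthonormality preserves energy
    expect_equal(sum(unlist(got)^2), sum(as.numeric(img)^2),
                 tolerance = 1e-6)
  }
  # odd extents are edge-replicated, not an error
  expect_length(dwt_subband_features(random_gray(5, 7, seed = 3)), 4)
})

test_that("Haar features resolve constants and oriented steps", {
  flat <- matrix(60L, 8, 8)
  f <- dwt_subband_features(flat)
  expect_equal(unname(f), c(120, 0, 0, 0))   # LL doubles, details vanish

  # vertical edge inside a column pair: horizontal detail only
  step <- cbind(matrix(0L, 4, 1), matrix(100L, 4, 3))
  f <- dwt_subband_features(step)
  expect_equal(unname(f), c(150, 50, 0, 0))
})

test_that("histogram statistics match moment sums and conventions", {
  flat <- matrix(9L, 5, 5)
  expect_equal(unname(histogram_stats(flat)), c(9, 0, 0, 0, 0))

  half <- matrix(as.integer(rep(c(0L, 255L), 32)), 8, 8)
  h <- histogram_stats(half)
  expect_equal(h[["hist_mean"]], 127.5)
  expect_equal(h[["hist_skewness"]], 0)
  expect_equal(h[["hist_kurtosis"]], -2)

  set.seed(29)
  bell <- matrix(as.integer(rbinom(10000, 255, 0.5)), 100, 100)
  hb <- histogram_stats(bell)
  expect_lt(abs(hb[["hist_skewness"]]), 0.1)
  expect_lt(abs(hb[["hist_kurtosis"]]), 0.2)

  for (s in 1:5) {
    img <- random_gray(9, 11, seed = s)
    expect_equal(unname(histogram_stats(img)), oracle_hist_stats(img),
                 tolerance = 1e-9)
  }
})

test_that("the 14-value vector is ordered, finite and deterministic", {
  img <- random_gray(32, 32, seed = 41)
  fv <- extract_feature_vector(img)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_feature_vector(img))
  expect_equal(fv[["hist_variance"]], fv[["hist_sd"]]^2)

  flat <- matrix(30L, 16, 16)
  ff <- extract_feature_vector(flat)
  expect_equal(unname(ff),
               c(60, 0, 0, 0,  0, 1, 1, 0, 1,  30, 0, 0, 0, 0))
})

test_that("batch extraction writes and reads a provenance-tagged CSV", {
  imgs <- lapply(1:4, function(i) random_gray(16, 16, seed = i))
  df <- extract_features_batch(imgs, labels = c(0, 1, 2, 3))
  expect_identical(names(df), c("path", "label", feature_names()))
  f <- tempfile(fileext = ".csv")
  write_feature_table(df, f, provenance = list(seed = 1, config_hash = "ab"))
  expect_match(readLines(f, n = 1), "^# ")
  back <- read_feature_table(f)
  expect_equal(back$wav_LL, df$wav_LL, tolerance = 1e-6)
  expect_equal(back$label, df$label)
})
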