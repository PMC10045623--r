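# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (double loops, explicit transform
# matrices, definitional moment sums) so they cannot share a defect
# with the implementation they check.

# brute-force symmetric GLCM by enumerating every pixel pair
oracle_glcm <- function(lv, L, dy, dx) {
  cnt <- matrix(0, L, L)
  h <- nrow(lv); w <- ncol(lv)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    i2 <- i + dy; j2 <- j + dx
    if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w) {
      a <- lv[i, j]; b <- lv[i2, j2]
      cnt[a + 1, b + 1] <- cnt[a + 1, b + 1] + 1
      cnt[b + 1, a + 1] <- cnt[b + 1, a + 1] + 1
    }
  }
  cnt / sum(cnt)
}

# the five texture statistics by explicit double loop
oracle_glcm_feats <- function(p) {
  L <- nrow(p)
  mi <- 0; mj <- 0
  for (i in 1:L) for (j in 1:L) {
    mi <- mi + (i - 1) * p[i, j]
    mj <- mj + (j - 1) * p[i, j]
  }
  vi <- 0; vj <- 0; contrast <- 0; hom <- 0; ent <- 0; ener <- 0; cor <- 0
  for (i in 1:L) for (j in 1:L) {
    vi <- vi + (i - 1 - mi)^2 * p[i, j]
    vj <- vj + (j - 1 - mj)^2 * p[i, j]
    contrast <- contrast + p[i, j] * (i - j)^2
    hom <- hom + p[i, j] / (1 + (i - j)^2)
    if (p[i, j] > 0) ent <- ent - p[i, j] * log2(p[i, j])
    ener <- ener + p[i, j]^2
  }
  cor <- if (vi <= 0 || vj <= 0) 1 else {
    s <- 0
    for (i in 1:L) for (j in 1:L)
      s <- s + p[i, j] * (i - 1 - mi) * (j - 1 - mj)
    s / sqrt(vi * vj)
  }
  c(contrast = contrast, correlation = cor, homogeneity = hom,
    entropy = ent, energy = ener)
}

# orthonormal single-level Haar analysis matrix of even size n
haar_matrix <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n / 2)) {
    A[i, 2 * i - 1] <- 1 / sqrt(2); A[i, 2 * i] <- 1 / sqrt(2)
    A[n / 2 + i, 2 * i - 1] <- 1 / sqrt(2)
    A[n / 2 + i, 2 * i] <- -1 / sqrt(2)
  }
  A
}

# sub-bands via explicit matrix products: rows split vertically,
# columns horizontally; block layout [LL LH; HL HH]
oracle_haar_subbands <- function(m) {
  Ar <- haar_matrix(nrow(m)); Ac <- haar_matrix(ncol(m))
  Y <- Ar %*% m %*% t(Ac)
  hr <- nrow(m) / 2; hc <- ncol(m) / 2
  list(LL = Y[1:hr, 1:hc, drop = FALSE],
       LH = Y[1:hr, (hc + 1):(2 * hc), drop = FALSE],
       HL = Y[(hr + 1):(2 * hr), 1:hc, drop = FALSE],
       HH = Y[(hr + 1):(2 * hr), (hc + 1):(2 * hc), drop = FALSE])
}

# definitional central moment statistics
oracle_hist_stats <- function(img) {
  x <- as.numeric(img); n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  if (m2 <= 0) return(c(mu, 0, 0, 0, 0))
  c(mu, m2, sqrt(m2), m3 / m2^1.5, m4 / m2^2 - 3)
}

# four well-separated Gaussian clusters in 14 dimensions
make_clusters <- function(n_per_class = 30, seed = 42, sep = 3) {
  set.seed(seed)
  mu <- matrix(stats::rnorm(4 * 14, sd = sep), 4, 14)
  x <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(stats::rnorm(n_per_class * 14), n_per_class, 14),
          2, mu[k, ], "+")))
  list(x = x, y = rep(0:3, each = n_per_class))
}

random_gray <- function(h, w, seed) {
  set.seed(seed)
  matrix(as.integer(sample(0:255, h * w, replace = TRUE)), h, w)
}
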