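#' Hyperparameter ranges of the searched network
#'
#' The integer ranges of the 11 optimized hyperparameters: the structure
#' triple (counts of convolution, pooling and fully connected layers,
#' each 1-5) and the eight shared layer parameters. The published table
#' lists the FC width `op` range as the single value 1, which cannot
#' hold a classifier head; it is treated as a misprint and widened to
#' 4-128 (the output layer is always forced to the class count).
#'
#' @param which `"structure"` (3 rows) or `"layer"` (8 rows).
#' @return Integer matrix with columns `min`, `max` and one row per
#'   hyperparameter.
#' @export
genome_ranges <- function(which = c("structure", "layer")) {
  which <- match.arg(which)
  if (which == "structure") {
    m <- cbind(min = c(nc = 1L, np = 1L, nf = 1L),
               max = c(nc = 5L, np = 5L, nf = 5L))
  } else {
    m <- cbind(min = c(op = 4L, p_pp = 0L, p_ss = 1L, p_fs = 1L,
                       c_ss = 1L, c_pp = 0L, c_fs = 1L, c_nf = 1L),
               max = c(op = 128L, p_pp = 1L, p_ss = 5L, p_fs = 13L,
                       c_ss = 5L, c_pp = 1L, c_fs = 13L, c_nf = 64L))
  }
  m
}

#' Decode a real position into an integer genome
#'
#' Each coordinate is floored (the integer nearest from below) and then
#' clamped into its range, so any real vector decodes to a valid genome.
#'
#' @param position Numeric vector.
#' @param ranges Integer matrix with columns `min`, `max`
#'   (see [genome_ranges()]); one row per coordinate.
#' @return Named integer vector.
#' @export
decode_genome <- function(position, ranges) {
  if (length(position) != nrow(ranges))
    stop("position length does not match the range table")
  g <- floor(position)
  g <- pmin(pmax(g, ranges[, "min"]), ranges[, "max"])
  stats::setNames(as.integer(g), rownames(ranges))
}

#' Structure genome constructor
#'
#' @param nc,np,nf Counts of convolution, pooling and fully connected
#'   layers, each an integer in 1-5.
#' @return Named integer vector of class `structure_genome`.
#' @export
structure_genome <- function(nc, np, nf) {
  g <- c(nc = as.integer(nc), np = as.integer(np), nf = as.integer(nf))
  r <- genome_ranges("structure")
  if (any(g < r[, "min"]) || any(g > r[, "max"]))
    stop("structure genome outside its ranges")
  structure(g, class = "structure_genome")
}

#' Layer genome constructor
#'
#' @param op FC layer width (4-128).
#' @param p_pp,p_ss,p_fs Pooling padding flag (0 valid / 1 same), stride
#'   (1-5) and window size (1-13), shared by all pooling layers.
#' @param c_ss,c_pp,c_fs,c_nf Convolution stride (1-5), padding flag,
#'   kernel size (1-13) and filter count (1-64), shared by all
#'   convolution layers.
#' @return Named integer vector of class `layer_genome`.
#' @export
layer_genome <- function(op, p_pp, p_ss, p_fs, c_ss, c_pp, c_fs, c_nf) {
  g <- c(op = op, p_pp = p_pp, p_ss = p_ss, p_fs = p_fs,
         c_ss = c_ss, c_pp = c_pp, c_fs = c_fs, c_nf = c_nf)
  g <- stats::setNames(as.integer(g), names(g))
  r <- genome_ranges("layer")
  if (any(g < r[, "min"]) || any(g > r[, "max"]))
    stop("layer genome outside its ranges")
  structure(g, class = "layer_genome")
}

#' Phase-1 default layer genome
#'
#' Midpoints (floored) of the layer ranges, held fixed while the
#' structure triple is searched so that structure fitness values are
#' comparable across candidates.
#'
#' @return A [layer_genome()].
#' @export
default_layer_genome <- function() {
  r <- genome_ranges("layer")
  g <- floor((r[, "min"] + r[, "max"]) / 2)
  do.call(layer_genome, as.list(g))
}

# output extent of a conv/pool axis; NA means the layer cannot apply
axis_out <- function(d, k, s, same) {
  if (same) return(as.integer(ceiling(d / s)))
  if (d < k) return(NA_integer_)
  as.integer((d - k) %/% s + 1L)
}

#' Assemble a network configuration from genomes
#'
#' Layer order: alternating convolution/pooling pairs for
#' `min(nc, np)`, then surplus convolutions, then surplus poolings, then
#' `nf` fully connected ReLU layers of `op` units and a final
#' `n_classes`-way softmax head. All convolutions share
#' `(c_fs, c_nf, c_ss, c_pp)` and all poolings `(p_fs, p_ss, p_pp)`
#' (padding flag 0 = valid, 1 = same). Any convolution or pooling whose
#' application would shrink an extent below 1 (valid padding with a
#' window larger than the current extent) is skipped and counted in
#' `$skipped`, so every in-range genome yields a runnable network.
#'
#' @param structure A [structure_genome()] (or named vector nc/np/nf).
#' @param layer A [layer_genome()] (or named vector of the 8 values).
#' @param input_shape Integer vector: length 1 for feature vectors
#'   (1-D convolutions), length 2 for `c(height, width)` images.
#' @param channels Input channel count (default 1).
#' @param n_classes Output class count K (default 4).
#' @return An object of class `cnn_config`.
#' @export
assemble_architecture <- function(structure, layer, input_shape = 14L,
                                  channels = 1L, n_classes = 4L) {
  input_shape <- as.integer(input_shape)
  if (length(input_shape) < 1L || any(input_shape < 1L))
    stop("`input_shape` must hold positive extents")
  if (!length(input_shape) %in% c(1L, 2L))
    stop("`input_shape` must have length 1 (features) or 2 (images)")
  s <- structure; l <- layer
  kinds <- c(rep(c("conv", "pool"), min(s[["nc"]], s[["np"]])),
             rep("conv", s[["nc"]] - min(s[["nc"]], s[["np"]])),
             rep("pool", s[["np"]] - min(s[["nc"]], s[["np"]])))
  d <- input_shape; ch <- channels
  layers <- list(); skipped <- 0L
  for (kind in kinds) {
    if (kind == "conv") {
      k <- l[["c_fs"]]; st <- l[["c_ss"]]; same <- l[["c_pp"]] == 1L
      nf <- l[["c_nf"]]
    } else {
      k <- l[["p_fs"]]; st <- l[["p_ss"]]; same <- l[["p_pp"]] == 1L
      nf <- ch
    }
    out <- vapply(d, axis_out, integer(1), k = k, s = st, same = same)
    if (anyNA(out) || any(out < 1L)) {
      skipped <- skipped + 1L
      next
    }
    pads <- vapply(seq_along(d), function(ax) {
      if (!same) return(0L)
      as.integer(max((out[ax] - 1L) * st + k - d[ax], 0L))
    }, integer(1))
    layers[[length(layers) + 1L]] <-
      list(type = kind, k = k, stride = st, same = same,
           pad = pads, in_dim = d, out_dim = out,
           in_ch = ch, filters = nf)
    d <- out
    if (kind == "conv") ch <- nf
  }
  in_units <- prod(d) * ch
  for (f in seq_len(s[["nf"]])) {
    layers[[length(layers) + 1L]] <-
      list(type = "fc", in_units = in_units, out_units = l[["op"]],
           relu = TRUE)
    in_units <- l[["op"]]
  }
  layers[[length(layers) + 1L]] <-
    list(type = "fc", in_units = in_units, out_units = as.integer(n_classes),
         relu = FALSE)
  out <- list(layers = layers, input_shape = input_shape,
              channels = as.integer(channels),
              n_classes = as.integer(n_classes),
              mode = if (length(input_shape) == 1L) "1d" else "2d",
              skipped = skipped,
              structure = stats::setNames(as.integer(s), names(s)),
              layer = stats::setNames(as.integer(l), names(l)))
  class(out) <- "cnn_config"
  out
}

# ---- parameter initialization --------------------------------------------

init_cnn <- function(cfg) {
  lapply(cfg$layers, function(ly) {
    if (ly$type == "conv") {
      fan_in <- prod(rep(ly$k, length(ly$in_dim))) * ly$in_ch
      list(W = matrix(stats::rnorm(fan_in * ly$filters, 0, sqrt(2 / fan_in)),
                      fan_in, ly$filters),
           b = numeric(ly$filters))
    } else if (ly$type == "fc") {
      if (!ly$relu) {
        # zero-init softmax head: an untrained net predicts the uniform
        # distribution, so its loss on balanced data is exactly log K
        return(list(W = matrix(0, ly$in_units, ly$out_units),
                    b = numeric(ly$out_units)))
      }
      sdv <- sqrt(2 / ly$in_units)
      list(W = matrix(stats::rnorm(ly$in_units * ly$out_units, 0, sdv),
                      ly$in_units, ly$out_units),
           b = numeric(ly$out_units))
    } else NULL
  })
}

# ---- 1-D layers -----------------------------------------------------------

pad_axis1d <- function(X, pad, value = 0) {
  if (pad == 0L) return(X)
  n <- dim(X)[1]; L <- dim(X)[2]; C <- dim(X)[3]
  pl <- pad %/% 2L; pr <- pad - pl
  Xp <- array(value, c(n, L + pad, C))
  Xp[, pl + seq_len(L), ] <- X
  Xp
}

# im2col gather in C++, arithmetic in BLAS
conv1d_fwd <- function(X, par, ly) {
  n <- dim(X)[1]
  Xp <- pad_axis1d(X, ly$pad[1])
  outL <- ly$out_dim[1]
  M <- cpp_im2col1d(Xp, dim(Xp), ly$k, ly$stride, outL)
  out <- M %*% par$W
  out <- out + rep(par$b, each = n * outL)
  out[out < 0] <- 0                          # ReLU
  dim(out) <- c(n, outL, ly$filters)
  list(out = out, M = M, padL = dim(Xp)[2])
}

conv1d_bwd <- function(dOut, cache, par, ly, n) {
  outL <- ly$out_dim[1]
  dmat <- dOut
  dim(dmat) <- c(n * outL, ly$filters)
  dmat[cache$out <= 0] <- 0                  # ReLU mask (same memory layout)
  dW <- crossprod(cache$M, dmat)
  db <- colSums(dmat)
  dM <- tcrossprod(dmat, par$W)
  dXp <- cpp_col2im1d(dM, c(n, cache$padL, ly$in_ch), ly$k, ly$stride, outL)
  pad <- ly$pad[1]; pl <- pad %/% 2L
  list(dX = dXp[, pl + seq_len(ly$in_dim[1]), , drop = FALSE],
       dW = dW, db = db)
}

pool1d_fwd <- function(X, ly) {
  Xp <- pad_axis1d(X, ly$pad[1], value = -Inf)
  res <- cpp_pool1d_fwd(Xp, dim(Xp), ly$k, ly$stride, ly$out_dim[1])
  list(out = res$out, arg = res$arg, padL = dim(Xp)[2])
}

pool1d_bwd <- function(dOut, cache, ly, n) {
  dXp <- cpp_pool1d_bwd(cache$arg, dOut,
                        c(n, ly$out_dim[1], ly$in_ch), cache$padL)
  pad <- ly$pad[1]; pl <- pad %/% 2L
  list(dX = dXp[, pl + seq_len(ly$in_dim[1]), , drop = FALSE])
}

# ---- 2-D layers (image mode; desk-scale sizes) ---------------------------

pad_axes2d <- function(X, pads, value = 0) {
  if (all(pads == 0L)) return(X)
  n <- dim(X)[1]; H <- dim(X)[2]; W <- dim(X)[3]; C <- dim(X)[4]
  pt <- pads[1] %/% 2L; plft <- pads[2] %/% 2L
  Xp <- array(value, c(n, H + pads[1], W + pads[2], C))
  Xp[, pt + seq_len(H), plft + seq_len(W), ] <- X
  Xp
}

conv2d_fwd <- function(X, par, ly) {
  n <- dim(X)[1]
  Xp <- pad_axes2d(X, ly$pad)
  k <- ly$k; s <- ly$stride; C <- ly$in_ch; nf <- ly$filters
  oh <- ly$out_dim[1]; ow <- ly$out_dim[2]
  cols <- array(0, c(n, k * k * C, oh * ow))
  out <- array(0, c(n, oh, ow, nf))
  for (ty in seq_len(oh)) for (tx in seq_len(ow)) {
    sy <- (ty - 1L) * s + 1L; sx <- (tx - 1L) * s + 1L
    win <- Xp[, sy:(sy + k - 1L), sx:(sx + k - 1L), , drop = FALSE]
    dim(win) <- c(n, k * k * C)
    p <- (tx - 1L) * oh + ty
    cols[, , p] <- win
    out[, ty, tx, ] <- win %*% par$W + matrix(par$b, n, nf, byrow = TRUE)
  }
  mask <- out > 0
  out[!mask] <- 0
  list(out = out, cols = cols, mask = mask, padHW = dim(Xp)[2:3])
}

conv2d_bwd <- function(dOut, cache, par, ly, n) {
  dOut[!cache$mask] <- 0
  k <- ly$k; s <- ly$stride; C <- ly$in_ch; nf <- ly$filters
  oh <- ly$out_dim[1]; ow <- ly$out_dim[2]
  dW <- matrix(0, k * k * C, nf); db <- numeric(nf)
  dXp <- array(0, c(n, cache$padHW[1], cache$padHW[2], C))
  for (ty in seq_len(oh)) for (tx in seq_len(ow)) {
    dout_t <- matrix(dOut[, ty, tx, ], n, nf)
    p <- (tx - 1L) * oh + ty
    col_t <- matrix(cache$cols[, , p], n, k * k * C)
    dW <- dW + crossprod(col_t, dout_t)
    db <- db + colSums(dout_t)
    dcol <- dout_t %*% t(par$W)
    dim(dcol) <- c(n, k, k, C)
    sy <- (ty - 1L) * s + 1L; sx <- (tx - 1L) * s + 1L
    dXp[, sy:(sy + k - 1L), sx:(sx + k - 1L), ] <-
      dXp[, sy:(sy + k - 1L), sx:(sx + k - 1L), , drop = FALSE] + dcol
  }
  pt <- ly$pad[1] %/% 2L; plft <- ly$pad[2] %/% 2L
  list(dX = dXp[, pt + seq_len(ly$in_dim[1]), plft + seq_len(ly$in_dim[2]), ,
                drop = FALSE],
       dW = dW, db = db)
}

pool2d_fwd <- function(X, ly) {
  n <- dim(X)[1]; C <- ly$in_ch
  Xp <- pad_axes2d(X, ly$pad, value = -Inf)
  k <- ly$k; s <- ly$stride
  oh <- ly$out_dim[1]; ow <- ly$out_dim[2]
  ph <- dim(Xp)[2]
  out <- array(0, c(n, oh, ow, C))
  arg <- array(0L, c(n, oh, ow, C))     # linear (y,x) index into padded grid
  for (ty in seq_len(oh)) for (tx in seq_len(ow)) {
    sy <- (ty - 1L) * s + 1L; sx <- (tx - 1L) * s + 1L
    best <- matrix(-Inf, n, C); bidx <- matrix(1L, n, C)
    for (ky in 0:(k - 1L)) for (kx in 0:(k - 1L)) {
      cur <- matrix(Xp[, sy + ky, sx + kx, ], n, C)
      upd <- cur > best
      best[upd] <- cur[upd]
      bidx[upd] <- (sy + ky) + ((sx + kx) - 1L) * ph
    }
    out[, ty, tx, ] <- best
    arg[, ty, tx, ] <- bidx
  }
  list(out = out, arg = arg, padHW = dim(Xp)[2:3])
}

pool2d_bwd <- function(dOut, cache, ly, n) {
  C <- ly$in_ch
  ph <- cache$padHW[1]; pw <- cache$padHW[2]
  dXp <- array(0, c(n, ph, pw, C))
  rows <- rep(seq_len(n), C)
  chs <- rep(seq_len(C), each = n)
  for (ty in seq_len(ly$out_dim[1])) for (tx in seq_len(ly$out_dim[2])) {
    yx <- as.vector(cache$arg[, ty, tx, ])
    li <- rows + (yx - 1L) * n + (chs - 1L) * n * ph * pw
    dXp[li] <- dXp[li] + as.vector(matrix(dOut[, ty, tx, ], n, C))
  }
  pt <- ly$pad[1] %/% 2L; plft <- ly$pad[2] %/% 2L
  list(dX = dXp[, pt + seq_len(ly$in_dim[1]), plft + seq_len(ly$in_dim[2]), ,
                drop = FALSE])
}

# ---- whole-network forward / backward ------------------------------------

net_forward <- function(params, cfg, X, keep = FALSE) {
  n <- dim(X)[1]
  caches <- vector("list", length(cfg$layers))
  cur <- X
  flat <- FALSE
  for (li in seq_along(cfg$layers)) {
    ly <- cfg$layers[[li]]
    if (ly$type == "fc" && !flat) {
      dim(cur) <- c(n, prod(dim(cur)[-1]))
      flat <- TRUE
    }
    if (ly$type == "conv") {
      cc <- if (cfg$mode == "1d") conv1d_fwd(cur, params[[li]], ly)
            else conv2d_fwd(cur, params[[li]], ly)
      if (keep) caches[[li]] <- cc else caches[[li]] <- NULL
      cur <- cc$out
    } else if (ly$type == "pool") {
      cc <- if (cfg$mode == "1d") pool1d_fwd(cur, ly) else pool2d_fwd(cur, ly)
      if (keep) caches[[li]] <- cc
      cur <- cc$out
    } else {
      z <- cur %*% params[[li]]$W +
        matrix(params[[li]]$b, n, ly$out_units, byrow = TRUE)
      if (ly$relu) {
        mask <- z > 0
        z[!mask] <- 0
        if (keep) caches[[li]] <- list(X = cur, mask = mask)
      } else if (keep) caches[[li]] <- list(X = cur)
      cur <- z
    }
  }
  list(logits = cur, caches = caches)
}

net_backward <- function(dlogits, fw, params, cfg, n) {
  grads <- vector("list", length(cfg$layers))
  dcur <- dlogits
  for (li in rev(seq_along(cfg$layers))) {
    ly <- cfg$layers[[li]]
    cc <- fw$caches[[li]]
    if (ly$type == "fc") {
      if (ly$relu) dcur[!cc$mask] <- 0
      grads[[li]] <- list(dW = crossprod(cc$X, dcur), db = colSums(dcur))
      dcur <- dcur %*% t(params[[li]]$W)
    } else if (ly$type == "conv") {
      if (is.matrix(dcur))
        dim(dcur) <- c(n, ly$out_dim, ly$filters)
      g <- if (cfg$mode == "1d") conv1d_bwd(dcur, cc, params[[li]], ly, n)
           else conv2d_bwd(dcur, cc, params[[li]], ly, n)
      grads[[li]] <- list(dW = g$dW, db = g$db)
      dcur <- g$dX
    } else {
      if (is.matrix(dcur))
        dim(dcur) <- c(n, ly$out_dim, ly$in_ch)
      g <- if (cfg$mode == "1d") pool1d_bwd(dcur, cc, ly, n)
           else pool2d_bwd(dcur, cc, ly, n)
      dcur <- g$dX
    }
  }
  grads
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

xent_loss <- function(probs, y) {
  n <- nrow(probs)
  -mean(log(pmax(probs[cbind(seq_len(n), y + 1L)], 1e-12)))
}

#' Training settings for the classifier
#'
#' Plain mini-batch stochastic gradient descent on the softmax
#' cross-entropy; no momentum or adaptive step sizes. Defaults are sized
#' for the short probe trainings used inside a fitness evaluation.
#'
#' @param learning_rate SGD step size (default 0.01).
#' @param epochs Epochs per training run (>= 0; 0 returns the
#'   initialized network, whose loss on balanced data sits at chance,
#'   `-log(1/K)`).
#' @param batch_size Mini-batch size (default 16).
#' @param seed Integer seed driving initialization and batch shuffling.
#' @return An object of class `train_settings`.
#' @export
train_settings <- function(learning_rate = 0.01, epochs = 5L,
                           batch_size = 16L, seed = 1L) {
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("`learning_rate` must be > 0")
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (is.na(epochs) || epochs < 0L) stop("`epochs` must be >= 0")
  if (is.na(batch_size) || batch_size < 1L) stop("`batch_size` must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, seed = as.integer(seed)),
            class = "train_settings")
}

# coerce user input into the network's array layout and normalize
prepare_input <- function(x, cfg, norm) {
  if (cfg$mode == "1d") {
    x <- as.matrix(x)
    if (ncol(x) != cfg$input_shape)
      stop("input width does not match the network's input shape")
    x <- sweep(sweep(x, 2L, norm$center), 2L, norm$scale, "/")
    array(x, c(nrow(x), ncol(x), 1L))
  } else {
    if (is.list(x)) {
      n <- length(x)
      a <- array(0, c(n, cfg$input_shape))
      for (i in seq_len(n)) a[i, , ] <- x[[i]]
      x <- a
    }
    if (!all(dim(x)[2:3] == cfg$input_shape))
      stop("input image shape does not match the network's input shape")
    array(x / norm$scale, c(dim(x)[1], cfg$input_shape, 1L))
  }
}

#' Train the classifier by mini-batch gradient descent
#'
#' Minimizes the softmax cross-entropy for `settings$epochs` epochs.
#' Feature-mode inputs are z-scored with training-set statistics (stored
#' in the model); image-mode inputs are scaled to `[0, 1]`. The epoch
#' loss history is the full-training-set loss evaluated after each
#' epoch. Deterministic given `settings$seed`.
#'
#' @param cfg A [assemble_architecture()] configuration.
#' @param x Feature matrix (n x input_shape) in `"1d"` mode, or a list /
#'   array of images in `"2d"` mode.
#' @param y Integer labels in `0 .. n_classes - 1`.
#' @param settings A [train_settings()].
#' @return An object of class `cnn_model` with the fitted parameters,
#'   the normalization statistics, `loss_history` and `final_loss`.
#' @export
train_network <- function(cfg, x, y, settings = train_settings()) {
  stopifnot(inherits(cfg, "cnn_config"))
  y <- as.integer(y)
  if (length(y) == 0L) stop("training data must be non-empty")
  if (any(y < 0L) || any(y >= cfg$n_classes))
    stop("labels must lie in 0 .. n_classes - 1")
  set.seed(settings$seed)
  if (cfg$mode == "1d") {
    xm <- as.matrix(x)
    ctr <- colMeans(xm)
    scl <- apply(xm, 2L, stats::sd)
    scl[!is.finite(scl) | scl < 1e-12] <- 1
    norm <- list(center = ctr, scale = scl)
  } else {
    norm <- list(scale = 255)
  }
  X <- prepare_input(x, cfg, norm)
  n <- dim(X)[1]
  if (n != length(y)) stop("x and y sizes disagree")

  params <- init_cnn(cfg)
  K <- cfg$n_classes
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y + 1L)] <- 1
  lr <- settings$learning_rate

  full_loss <- function() {
    fw <- net_forward(params, cfg, X, keep = FALSE)
    xent_loss(softmax_rows(fw$logits), y)
  }

  loss_hist <- numeric(0)
  if (settings$epochs > 0L) {
    take <- function(a, idx) {           # slice leading dim of the input array
      if (cfg$mode == "1d") a[idx, , , drop = FALSE]
      else a[idx, , , , drop = FALSE]
    }
    for (ep in seq_len(settings$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = settings$batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + settings$batch_size - 1L, n)]
        nb <- length(idx)
        Xb <- take(X, idx)
        fw <- net_forward(params, cfg, Xb, keep = TRUE)
        probs <- softmax_rows(fw$logits)
        loss <- xent_loss(probs, y[idx])
        if (!is.finite(loss))
          stop("training diverged: non-finite loss")
        dlogits <- (probs - Y[idx, , drop = FALSE]) / nb
        grads <- net_backward(dlogits, fw, params, cfg, nb)
        for (li in seq_along(params)) {
          if (is.null(grads[[li]])) next
          params[[li]]$W <- params[[li]]$W - lr * grads[[li]]$dW
          params[[li]]$b <- params[[li]]$b - lr * grads[[li]]$db
        }
      }
      loss_hist <- c(loss_hist, full_loss())
    }
  }
  fl <- if (length(loss_hist)) loss_hist[length(loss_hist)] else full_loss()
  if (!is.finite(fl)) stop("training diverged: non-finite loss")
  structure(list(cfg = cfg, params = params, norm = norm,
                 loss_history = loss_hist, final_loss = fl,
                 settings = settings),
            class = "cnn_model")
}

#' Predict class probabilities and labels
#'
#' @param model A fitted (or merely initialized) [train_network()] model.
#' @param x New inputs in the same form the model was trained on.
#' @return List with `prob` (n x K matrix, rows summing to 1) and
#'   `label` (integer vector in `0 .. K - 1`; argmax, ties to the lowest
#'   class index).
#' @export
predict_cnn <- function(model, x) {
  stopifnot(inherits(model, "cnn_model"))
  X <- prepare_input(x, model$cfg, model$norm)
  fw <- net_forward(model$params, model$cfg, X, keep = FALSE)
  probs <- softmax_rows(fw$logits)
  list(prob = probs, label = max.col(probs, ties.method = "first") - 1L)
}
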