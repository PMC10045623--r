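test_that("genome decoding floors and clamps into the published ranges", {
  rs <- genome_ranges("structure")
  expect_equal(unname(decode_genome(c(2.7, 1.2, 4.9), rs)), c(2L, 1L, 4L))
  expect_equal(unname(decode_genome(c(-3, 0.5, 99), rs)), c(1L, 1L, 5L))
  rl <- genome_ranges("layer")
  expect_identical(decode_genome(rep(64.9, 8), rl)[["c_nf"]], 64L)
  expect_error(decode_genome(1:2, rs), "length")

  set.seed(5)
  for (i in 1:50) {
    g <- decode_genome(stats::rnorm(8, sd = 200), rl)
    expect_true(all(g >= rl[, "min"] & g <= rl[, "max"]))
  }
})

test_that("genome constructors reject out-of-range values", {
  expect_error(structure_genome(0, 1, 1), "outside")
  expect_error(structure_genome(1, 6, 1), "outside")
  expect_error(layer_genome(4, 0, 1, 1, 1, 0, 1, 65), "outside")
  expect_silent(layer_genome(4, 0, 1, 1, 1, 0, 1, 64))
  ld <- default_layer_genome()
  rl <- genome_ranges("layer")
  expect_equal(unname(unclass(ld)), unname(floor((rl[, 1] + rl[, 2]) / 2)))
})

test_that("assembly builds conv/pool/fc stacks and always ends in K softmax", {
  cfg <- assemble_architecture(structure_genome(1, 1, 1),
                               default_layer_genome(), 14)
  types <- vapply(cfg$layers, `[[`, character(1), "type")
  expect_true(identical(types, c("conv", "pool", "fc", "fc")) ||
              identical(types, c("conv", "fc", "fc")))  # pool may be skipped
  last <- cfg$layers[[length(cfg$layers)]]
  expect_equal(last$out_units, 4L)
  expect_false(last$relu)

  # degenerate: huge valid-padding windows on a short signal are skipped
  cfg2 <- assemble_architecture(structure_genome(5, 5, 1),
                                layer_genome(8, 0, 5, 13, 5, 0, 13, 4), 14)
  expect_gt(cfg2$skipped, 0)
  expect_equal(cfg2$layers[[length(cfg2$layers)]]$out_units, 4L)

  expect_error(assemble_architecture(structure_genome(1, 1, 1),
                                     default_layer_genome(), integer(0)),
               "input_shape")
})

test_that("every in-range genome yields a runnable network (totality fuzz)", {
  set.seed(9)
  x <- matrix(stats::rnorm(8 * 14), 8, 14)
  for (i in 1:15) {
    s <- decode_genome(stats::runif(3, 1, 6), genome_ranges("structure"))
    l <- decode_genome(stats::runif(8, c(4, 0, 1, 1, 1, 0, 1, 1),
                                    c(129, 2, 6, 14, 6, 2, 14, 65)),
                       genome_ranges("layer"))
    cfg <- assemble_architecture(do.call(structure_genome, as.list(s)),
                                 do.call(layer_genome, as.list(l)), 14)
    m <- train_network(cfg, x, rep(0:3, 2), train_settings(epochs = 0))
    p <- predict_cnn(m, x)
    expect_equal(dim(p$prob), c(8L, 4L))
  }
})

test_that("training separates four feature clusters and is reproducible", {
  d <- make_clusters(30, seed = 42)
  cfg <- assemble_architecture(structure_genome(1, 1, 1),
                               default_layer_genome(), 14)
  m <- train_network(cfg, d$x, d$y, train_settings(epochs = 5, seed = 7))
  p <- predict_cnn(m, d$x)
  expect_gte(mean(p$label == d$y), 0.95)
  m2 <- train_network(cfg, d$x, d$y, train_settings(epochs = 5, seed = 7))
  expect_identical(m$final_loss, m2$final_loss)
  expect_identical(predict_cnn(m2, d$x)$label, p$label)
})

test_that("an untrained network sits at chance loss on balanced data", {
  d <- make_clusters(8, seed = 3)
  cfg <- assemble_architecture(structure_genome(2, 1, 1),
                               default_layer_genome(), 14)
  m <- train_network(cfg, d$x, d$y, train_settings(epochs = 0, seed = 1))
  expect_equal(m$final_loss, log(4), tolerance = 1e-12)
  expect_length(m$loss_history, 0)
})

test_that("full-batch descent with a small step never increases the loss", {
  d <- make_clusters(10, seed = 8)
  cfg <- assemble_architecture(structure_genome(1, 1, 1),
                               default_layer_genome(), 14)
  m <- train_network(cfg, d$x, d$y,
                     train_settings(learning_rate = 0.005, epochs = 15,
                                    batch_size = 40, seed = 2))
  expect_true(all(diff(c(log(4), m$loss_history)) <= 1e-10))
})

test_that("training reports divergence instead of silently failing", {
  d <- make_clusters(10, seed = 8)
  cfg <- assemble_architecture(structure_genome(1, 1, 2),
                               default_layer_genome(), 14)
  expect_error(
    train_network(cfg, d$x, d$y,
                  train_settings(learning_rate = 1e8, epochs = 5, seed = 1)),
    "diverged")
})

test_that("prediction returns proper probabilities and held-out skill", {
  d <- make_clusters(40, seed = 12)
  tr <- c(1:30, 41:70, 81:110, 121:150)
  te <- setdiff(seq_len(160), tr)
  cfg <- assemble_architecture(structure_genome(1, 1, 1),
                               default_layer_genome(), 14)
  m <- train_network(cfg, d$x[tr, ], d$y[tr], train_settings(seed = 4))
  p <- predict_cnn(m, d$x[te, ])
  expect_equal(rowSums(p$prob), rep(1, length(te)), tolerance = 1e-6)
  expect_gt(mean(p$label == d$y[te]), 0.25)
  # duplicates map identically
  p2 <- predict_cnn(m, d$x[c(te[1], te[1]), ])
  expect_identical(p2$prob[1, ], p2$prob[2, ])
  expect_error(predict_cnn(m, d$x[, 1:5]), "input width")
})

test_that("backpropagation agrees with numerical differentiation", {
  set.seed(5)
  x <- matrix(stats::rnorm(6 * 14), 6, 14)
  y <- sample(0:3, 6, TRUE)
  cfg <- assemble_architecture(structure_genome(2, 2, 1),
                               layer_genome(6, 1, 2, 3, 2, 0, 3, 3), 14)
  params <- local({ set.seed(9); remoraCNN:::init_cnn(cfg) })
  lo <- length(params)
  set.seed(11)
  params[[lo]]$W[] <- stats::rnorm(length(params[[lo]]$W), 0, 0.3)
  X <- array(scale(x), c(6, 14, 1))
  loss_at <- function(p) {
    fw <- remoraCNN:::net_forward(p, cfg, X)
    remoraCNN:::xent_loss(remoraCNN:::softmax_rows(fw$logits), y)
  }
  fw <- remoraCNN:::net_forward(params, cfg, X, keep = TRUE)
  probs <- remoraCNN:::softmax_rows(fw$logits)
  dlog <- (probs - (outer(y, 0:3, "==") + 0)) / 6
  gr <- remoraCNN:::net_backward(dlog, fw, params, cfg, 6)
  base <- loss_at(params)
  eps <- 1e-6
  set.seed(13)
  for (li in seq_along(params)) {
    if (is.null(params[[li]])) next
    for (f in c("W", "b")) {
      picks <- sample(seq_along(params[[li]][[f]]),
                      min(5, length(params[[li]][[f]])))
      for (ix in picks) {
        p2 <- params
        p2[[li]][[f]][ix] <- p2[[li]][[f]][ix] + eps
        num <- (loss_at(p2) - base) / eps
        ana <- if (f == "W") gr[[li]]$dW[ix] else gr[[li]]$db[ix]
        expect_equal(num, ana, tolerance = 1e-3)
      }
    }
  }
})

test_that("the 2-D image mode trains and predicts", {
  set.seed(77)
  imgs <- lapply(1:24, function(i) {
    base <- matrix(as.integer(sample(40:200, 64, TRUE)), 8, 8)
    if (i %% 4 < 2) base[3:6, 3:6] <- 250L    # classes 0/1 carry a bright core
    base
  })
  y <- rep(0:3, 6)
  cfg <- assemble_architecture(structure_genome(1, 1, 1),
                               layer_genome(8, 1, 2, 2, 1, 1, 3, 4),
                               c(8, 8))
  expect_equal(cfg$mode, "2d")
  m <- train_network(cfg, imgs, y, train_settings(epochs = 2, seed = 5))
  p <- predict_cnn(m, imgs)
  expect_equal(rowSums(p$prob), rep(1, 24), tolerance = 1e-6)
  m2 <- train_network(cfg, imgs, y, train_settings(epochs = 2, seed = 5))
  expect_identical(m$final_loss, m2$final_loss)
})
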