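test_that("depth embedding is the position-wise affine map", {
  cfg <- tiny_config()
  m <- init_model(cfg, list(mean = 0, sd = 1), seed = 9)
  x <- c(0, 1.3, -0.4, 1.3)
  E <- embed_depth(x, m)
  expect_equal(dim(E), c(cfg$H, 4L))
  expect_equal(E[, 1], m$params$embed_b)             # affine at zero
  expect_equal(E[, 2], E[, 4])                       # equal depths, equal cols
  # independent per-column oracle
  for (j in seq_along(x)) {
    expect_equal(E[, j], m$params$embed_w * x[j] + m$params$embed_b,
                 tolerance = 1e-12)
  }
})

test_that("positional encoding follows the interleaved sin/cos construction", {
  cfg <- tiny_config(max_len = 10L)
  tgt <- list(start = 14600, end = 14900)
  pe <- positional_encoding(tgt, cfg, n_real = 10L)
  expect_equal(dim(pe), c(cfg$H, 11L))
  # token column has loc = 0: sin rows 0, cos rows 1
  expect_equal(pe[seq(1, cfg$H, 2), 1], rep(0, cfg$H / 2))
  expect_equal(pe[seq(2, cfg$H, 2), 1], rep(1, cfg$H / 2))
  expect_true(all(pe >= -1 & pe <= 1))
  # scalar oracle at the low end of the stated coordinate range
  locs <- seq(14600, 14900, length.out = 10)
  for (j in 0:(cfg$H / 2 - 1)) {
    expect_equal(pe[2 * j + 1, 2], sin(14600 / 10^(9 * 2 * j / cfg$H)))
    expect_equal(pe[2 * j + 2, 6], cos(locs[5] / 10^(9 * 2 * j / cfg$H)))
  }
  expect_error(positional_encoding(list(start = 10, end = 10), cfg), "start")
})

test_that("positional encoding separates the extremes of the coordinate range", {
  cfg <- model_config(H = 192L, L = 1L, heads = 8L, max_len = 4L)
  lo <- positional_encoding(list(start = 14600, end = 14601), cfg, n_real = 1L)
  hi <- positional_encoding(list(start = 290e6 - 1, end = 290e6), cfg,
                            n_real = 1L)
  expect_gt(max(abs(lo[, 5] - hi[, 5])), 0)
})

test_that("the compiled input stage equals the R composition of its parts", {
  cfg <- tiny_config(max_len = 12L)
  m <- init_model(cfg, list(mean = 0, sd = 1), seed = 4)
  x <- rnorm(7)
  enc <- encode_one(x, list(mean = 0, sd = 1), 12L, chrom_index = 5L,
                    start = 30000, end = 30007)
  locs <- seq(30000, 30007, length.out = 7)
  O0 <- cnvformer:::cpp_input_matrix(m$params, unclass(cfg), x, locs, 5L)
  ref <- t(cbind(m$params$C[, 5], embed_depth(x, m))) +
    t(positional_encoding(list(start = 30000, end = 30007), cfg, 7L)[, c(1, 7:13)])
  expect_equal(O0, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("forward output is a probability simplex and argmax drives the label", {
  cfg <- tiny_config()
  m <- init_model(cfg, list(mean = 10, sd = 4), seed = 6)
  set.seed(8)
  for (i in 1:5) {
    enc <- encode_one(runif(sample(5:60, 1), 0, 30), m$stats, 60L,
                      chrom_index = sample(24, 1))
    p <- predict_proba(m, enc)
    expect_gte(min(p$p_del, p$p_dup, p$p_nocall), 0)
    expect_equal(p$p_del + p$p_dup + p$p_nocall, 1, tolerance = 1e-6)
  }
  expect_equal(predict_label(0.1, 0.2, 0.7), "NOCALL")
  expect_equal(predict_label(0.5, 0.3, 0.2), "DEL")
  expect_equal(predict_label(0.34, 0.33, 0.33, min_call_prob = 0.4), "NOCALL")
  expect_equal(predict_label(0.34, 0.33, 0.33), "DEL")
})

test_that("padded positions never influence the forward pass", {
  cfg <- tiny_config()
  m <- init_model(cfg, list(mean = 10, sd = 4), seed = 6)
  set.seed(9)
  enc <- encode_one(runif(20, 0, 30), m$stats, 60L)
  p0 <- predict_proba(m, enc)
  for (i in 1:3) {
    enc2 <- enc
    d <- enc2$depth[[1]]
    d[!enc2$mask[[1]]] <- rnorm(sum(!enc2$mask[[1]]), sd = 10)  # scribble pads
    enc2$depth <- list(d)
    p1 <- predict_proba(m, enc2)
    expect_equal(unlist(p1[-1]), unlist(p0[-1]), tolerance = 1e-6)
  }
})

test_that("chromosome tokens and coordinates change the prediction context", {
  cfg <- tiny_config()
  m <- init_model(cfg, list(mean = 10, sd = 4), seed = 13)
  x <- runif(25, 0, 30)
  p1 <- predict_proba(m, encode_one(x, m$stats, 60L, chrom_index = 1L,
                                    start = 20000, end = 20025))
  p2 <- predict_proba(m, encode_one(x, m$stats, 60L, chrom_index = 2L,
                                    start = 5e6, end = 5e6 + 25))
  expect_gt(max(abs(unlist(p1[-1]) - unlist(p2[-1]))), 0)
  # token sensitivity alone: same coordinates, different chromosome
  p3 <- predict_proba(m, encode_one(x, m$stats, 60L, chrom_index = 2L,
                                    start = 20000, end = 20025))
  expect_gt(max(abs(unlist(p1[-1]) - unlist(p3[-1]))), 0)
  expect_error(predict_proba(m, encode_one(x, m$stats, 60L, chrom_index = 25L)),
               "chrom_index")
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(H = 8L, L = 2L, heads = 2L, max_len = 30L,
                      mlp_hidden = 6L)
  m <- init_model(cfg, list(mean = 0, sd = 1), seed = 42)
  set.seed(1)
  x <- rnorm(7); loc <- seq(15000, 15200, length.out = 7)
  loss_of <- function(params) {
    p <- cnvformer:::cpp_forward_batch(params, unclass(cfg), list(x),
                                       list(loc), 3L)
    -log(p[1, 2])
  }
  res <- cnvformer:::cpp_loss_grad_batch(m$params, unclass(cfg), list(x),
                                         list(loc), 3L, 2L, rep(1, 3))
  g <- cnvformer:::flatten_params(res$grads)
  p0 <- cnvformer:::flatten_params(m$params)
  eps <- 1e-6
  for (nm in names(p0)) {
    for (i in sample(length(p0[[nm]]), min(3, length(p0[[nm]])))) {
      pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p0; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(cnvformer:::rebuild_param_tree(pp, cfg$L)) -
                loss_of(cnvformer:::rebuild_param_tree(pm, cfg$L))) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("model bundles serialize and round-trip bit-exactly", {
  cfg <- tiny_config()
  m <- init_model(cfg, list(mean = 12.34567891234, sd = 3.14159265359),
                  seed = 77)
  m$history <- tibble::tibble(epoch = 1:2, loss = c(1.1, 0.5), lr = c(1e-3, 0))
  dir <- withr::local_tempdir()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(m2$params, m$params)
  expect_identical(m2$stats$mean, m$stats$mean)
  expect_identical(m2$stats$sd, m$stats$sd)
  set.seed(3)
  enc <- encode_one(runif(20, 5, 20), m$stats, 60L)
  expect_identical(predict_proba(m, enc), predict_proba(m2, enc))
})
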