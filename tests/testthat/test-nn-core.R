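# Gradient correctness of every layer primitive against central finite
# differences, plus optimizer and learning-rate schedule behavior.

ns <- asNamespace("refocus")

test_that("convolution, transpose convolution and pooling gradients are exact", {
  set.seed(42)
  for (pad in 0:1) {
    x <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
    w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
    b <- rnorm(3)
    y <- ns$nn_conv_fw(x, w, b, pad)
    gy <- array(rnorm(length(y)), dim(y))
    loss <- function(x_, w_, b_) sum(ns$nn_conv_fw(x_, w_, b_, pad) * gy)
    bw <- ns$nn_conv_bw(x, w, gy, pad)
    expect_lt(max_rel_err(bw$gx, num_grad(function(v) {
      x2 <- x; x2[] <- v; loss(x2, w, b)
    }, as.vector(x))), 1e-6)
    expect_lt(max_rel_err(as.vector(bw$gw), num_grad(function(v) {
      w2 <- w; w2[] <- v; loss(x, w2, b)
    }, as.vector(w))), 1e-6)
    expect_lt(max_rel_err(bw$gb, num_grad(function(v) loss(x, w, v), b)), 1e-6)
  }
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  w <- array(rnorm(2 * 2 * 3 * 2), c(2, 2, 3, 2))
  b <- rnorm(2)
  y <- ns$nn_tconv_fw(x, w, b)
  expect_equal(dim(y), c(8L, 8L, 2L))  # stride-2 doubling
  gy <- array(rnorm(length(y)), dim(y))
  bw <- ns$nn_tconv_bw(x, w, gy)
  loss <- function(x_, w_, b_) sum(ns$nn_tconv_fw(x_, w_, b_) * gy)
  expect_lt(max_rel_err(bw$gx, num_grad(function(v) {
    x2 <- x; x2[] <- v; loss(x2, w, b)
  }, as.vector(x))), 1e-6)
  expect_lt(max_rel_err(as.vector(bw$gw), num_grad(function(v) {
    w2 <- w; w2[] <- v; loss(x, w2, b)
  }, as.vector(w))), 1e-6)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  pl <- ns$nn_pool_fw(x)
  expect_equal(dim(pl$out), c(3L, 3L, 2L))
  gy <- array(rnorm(length(pl$out)), dim(pl$out))
  gx <- ns$nn_pool_bw(gy, pl$idx, 6, 6)
  gn <- num_grad(function(v) {
    x2 <- x; x2[] <- v; sum(ns$nn_pool_fw(x2)$out * gy)
  }, as.vector(x))
  expect_lt(max_rel_err(gx, gn), 1e-6)
})

test_that("instance normalization is per-channel exact and differentiable", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 3, mean = 2, sd = 3), c(5, 5, 3))
  gamma <- runif(3, 0.5, 1.5)
  beta <- rnorm(3)
  fw <- ns$nn_instnorm_fw(x, rep(1, 3), rep(0, 3))
  # with identity affine parameters every channel is standardized
  for (c in 1:3) {
    expect_lt(abs(mean(fw$y[, , c])), 1e-10)
    expect_equal(mean(fw$y[, , c]^2), 1, tolerance = 1e-3)
  }
  fw <- ns$nn_instnorm_fw(x, gamma, beta)
  gy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- ns$nn_instnorm_bw(fw, gamma, gy)
  loss <- function(x_, g_, b_) sum(ns$nn_instnorm_fw(x_, g_, b_)$y * gy)
  expect_lt(max_rel_err(bw$gx, num_grad(function(v) {
    x2 <- x; x2[] <- v; loss(x2, gamma, beta)
  }, as.vector(x))), 1e-5)
  expect_lt(max_rel_err(bw$ggamma,
                        num_grad(function(v) loss(x, v, beta), gamma)), 1e-6)
  expect_lt(max_rel_err(bw$gbeta,
                        num_grad(function(v) loss(x, gamma, v), beta)), 1e-6)
})

test_that("the SSIM loss gradient matches finite differences", {
  set.seed(3)
  a <- array(runif(13 * 13), c(13, 13, 1))
  b <- array(runif(13 * 13), c(13, 13, 1))
  ga <- ns$ssim_grad(a, b)
  gn <- num_grad(function(v) {
    a2 <- a; a2[] <- v; ssim(a2, b)
  }, as.vector(a), eps = 1e-5)
  expect_lt(max_rel_err(ga, gn), 1e-5)
  # loss-and-gradient wrapper for all three losses
  for (kind in c("ssim", "l1", "combinatory")) {
    lg <- ns$recon_loss_grad(b, a, kind)
    expect_true(is.finite(lg$loss))
    expect_equal(dim(lg$grad), dim(a))
  }
})

test_that("optimizers descend a quadratic and Nadam debiases correctly", {
  # minimize f(w) = sum(w^2)/2; gradient = w
  params <- list(layer = list(w = c(4, -2)))
  for (kind in c("sgd_momentum", "nadam")) {
    opt <- ns$opt_init(kind, params)
    p <- params
    for (i in 1:120) {
      st <- ns$opt_step(opt, p, list(layer = list(w = p$layer$w)), 0.05)
      opt <- st$opt
      p <- st$params
    }
    expect_lt(sum(p$layer$w^2), sum(params$layer$w^2) / 100)
  }
})

test_that("the learning-rate schedules match their closed forms", {
  sched <- list(kind = "halving", lr0 = 0.001)
  expect_equal(lr_at_epoch(sched, 0), 0.001)
  expect_equal(lr_at_epoch(sched, 4), 0.001)
  expect_equal(lr_at_epoch(sched, 5), 0.0005)
  for (e in 0:50) {
    expect_equal(lr_at_epoch(sched, e), 0.001 * 0.5^(e %/% 5))
  }
  ft <- list(kind = "finetune")
  expect_equal(lr_at_epoch(ft, 0), 2e-4)
  expect_equal(lr_at_epoch(ft, 24), 2e-4)
  expect_equal(lr_at_epoch(ft, 25), 1e-4)
  expect_equal(lr_at_epoch(ft, 30), 1e-4)
})
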