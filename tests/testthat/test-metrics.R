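test_that("roc_auc matches the brute-force pair statistic and pROC", {
  # printed example: labels 1,0,1,0 scores .9,.8,.7,.6 -> 3 of 4 pairs win
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))$auc, 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)  # all ties
  set.seed(11)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    r <- roc_auc(labels, scores)
    expect_equal(r$auc, pairwise_auc(labels, scores), tolerance = 1e-12)
    # curve invariants: monotone, anchored at (0,0) and (1,1)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(utils::tail(r$fpr, 1), utils::tail(r$tpr, 1)), c(1, 1))
    # invariance under strictly monotone score transforms
    expect_equal(roc_auc(labels, qlogis(scores / 2 + 0.25))$auc, r$auc)
  }
  # independent implementation cross-check
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(12)
    labels <- sample(0:1, 40, replace = TRUE)
    labels[1:2] <- c(0, 1)
    scores <- rnorm(40) + labels
    expect_equal(roc_auc(labels, scores)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "classes")
})

test_that("accuracy and confusion counts partition the sample", {
  labs <- c(rep("focused", 112), rep("defocused", 8))
  ac <- accuracy_confusion(labs, labs)
  expect_equal(ac$accuracy, 1.0)
  expect_equal(ac$confusion$fn + ac$confusion$fp, 0)
  expect_equal(ac$confusion$tp, 112)
  expect_equal(ac$confusion$tn, 8)
  flipped <- ifelse(labs == "focused", "defocused", "focused")
  expect_equal(accuracy_confusion(labs, flipped)$accuracy, 0)
  set.seed(3)
  pred <- sample(c("focused", "defocused"), 120, replace = TRUE)
  cf <- accuracy_confusion(labs, pred)$confusion
  expect_equal(cf$tp + cf$fp + cf$tn + cf$fn, 120)
  expect_error(accuracy_confusion(labs, pred[-1]), "mismatch")
})

test_that("ssim obeys its closed forms, symmetry and range", {
  img <- tiny_scene(64, 3, seed = 21)
  expect_equal(ssim(img, img), 1.0, tolerance = 1e-12)
  # constant 0 vs constant L at dynamic range L: C1 / (L^2 + C1)
  z <- array(0, c(16, 16, 1))
  o <- array(1, c(16, 16, 1))
  C1 <- 0.01^2
  expect_equal(ssim(z, o), C1 / (1 + C1), tolerance = 1e-12)
  b <- array(runif(64 * 64 * 3), c(64, 64, 3))
  expect_equal(ssim(img, b), ssim(b, img), tolerance = 1e-9)
  expect_true(ssim(img, b) >= -1 && ssim(img, b) <= 1)
  expect_error(ssim(img, z), "mismatch")
})

test_that("ssim agrees with the scikit-image reference on a small pair", {
  set.seed(5)
  a <- round(matrix(runif(24 * 24), 24, 24), 6)
  b <- round(matrix(runif(24 * 24), 24, 24), 6)
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  write.table(a, fa, row.names = FALSE, col.names = FALSE, sep = ",")
  write.table(b, fb, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- tryCatch(system2("python", c("-c", shQuote(paste0(
    "import numpy as np; from skimage.metrics import structural_similarity as s; ",
    "a=np.loadtxt('", fa, "',delimiter=','); b=np.loadtxt('", fb, "',delimiter=','); ",
    "print(float(s(a,b,gaussian_weights=True,sigma=1.5,use_sample_covariance=False,data_range=1.0)))"
  ))), stdout = TRUE, stderr = TRUE), error = function(e) NULL)
  skip_if(is.null(out) || length(out) == 0 ||
            is.na(suppressWarnings(as.numeric(out[length(out)]))),
          "python/scikit-image unavailable")
  ref <- as.numeric(out[length(out)])
  expect_equal(ssim(a, b), ref, tolerance = 1e-7)
})

test_that("the three losses satisfy their identities", {
  img <- tiny_scene(64, 2, seed = 23)
  expect_equal(ssim_loss(img, img), 0, tolerance = 1e-12)
  expect_equal(mae(img, img), 0)
  lc <- l1_and_combinatory_loss(img, img)
  expect_equal(lc$l1, 0)
  expect_equal(lc$combinatory, 0, tolerance = 1e-9)
  # mae closed forms and brute force
  expect_equal(mae(img, img + 0.1), 0.1)
  set.seed(1)
  b <- array(runif(length(img)), dim(img))
  expect_equal(mae(img, b), mean(abs(img - b)))
  # combinatory = l1 + 100 * ssim_loss on random pairs
  lc <- l1_and_combinatory_loss(img, b)
  expect_equal(lc$combinatory, lc$l1 + 100 * ssim_loss(img, b),
               tolerance = 1e-9)
  expect_gte(lc$combinatory, 100 * ssim_loss(img, b))
  # an anti-correlated structured pair drives SSIM negative, loss above 1
  x <- array(rep(c(0.2, 0.8), 200), c(20, 20, 1))
  expect_gt(ssim_loss(x, 1 - x), 1)
  # constant offset on a zero-variance pair: closed-form combinatory
  za <- array(0.4, c(16, 16, 1))
  zb <- array(0.5, c(16, 16, 1))
  lc0 <- l1_and_combinatory_loss(za, zb)
  expect_equal(lc0$l1, 0.1, tolerance = 1e-12)
  expect_equal(lc0$combinatory, 0.1 + 100 * (1 - ssim(za, zb)),
               tolerance = 1e-9)
})

test_that("intensity profiles sample bilinearly along segments", {
  # horizontal segment over a linear ramp reproduces the ramp
  ramp <- array(rep(seq(0, 1, length.out = 20), each = 20), c(20, 20, 1))
  prof <- intensity_profile(ramp, c(10, 1), c(10, 20))
  expect_length(prof, 20L)
  expect_equal(prof, seq(0, 1, length.out = 20), tolerance = 1e-12)
  # zero-length segment -> single sample; length convention round(len) + 1
  expect_length(intensity_profile(ramp, c(5, 5), c(5, 5)), 1L)
  expect_length(intensity_profile(ramp, c(1, 1), c(13, 10)), 16L)
  expect_error(intensity_profile(ramp, c(0, 1), c(5, 5)), "outside")
  # grayscale conversion is the channel mean
  rgb <- array(c(rep(0, 100), rep(0.3, 100), rep(0.6, 100)), c(10, 10, 3))
  expect_equal(intensity_profile(rgb, c(5, 2), c(5, 2)), 0.3)
})

test_that("cheat evaluation scores a set against itself at chance", {
  m <- build_sdcnn(conv_widths = c(4L, 8L), seed = 31)
  m$train_side <- 64L
  imgs <- lapply(1:6, function(i) tiny_scene(64, 2, seed = i))
  expect_equal(cheat_auc(m, imgs, imgs), 0.5, tolerance = 1e-9)
  expect_error(cheat_auc(m, imgs, list()), "empty")
})
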