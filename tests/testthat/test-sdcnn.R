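ns <- asNamespace("refocus")

test_that("the sorter outputs normalized probabilities at multiple input sides", {
  m <- build_sdcnn(seed = 1)  # default spec: widths 32/64/128/256
  for (side in c(134, 536)) {
    # default spec must accept both resolutions studied for the task
    x <- array(runif(side * side * 3), c(side, side, 3))
    p <- ns$sdcnn_forward(m, standardize(x))$prob
    expect_length(p, 2L)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
    if (side == 536) break  # one large side is enough for the expensive pass
  }
  # small-model contract: under a million trainable parameters
  expect_lt(n_parameters(m), 1e6)
  # per-layer count formula for the default spec, computed independently:
  # conv: kh*kw*cin*cout + cout; dense: 256*2 + 2
  widths <- c(32, 64, 128, 256)
  cin <- c(3, 32, 64, 128)
  expect_equal(n_parameters(m),
               sum(9 * cin * widths + widths) + 256 * 2 + 2)
  # grayscale input is replicated to three channels
  g <- array(runif(32 * 32), c(32, 32, 1))
  expect_equal(sum(ns$sdcnn_forward(m, g)$prob), 1, tolerance = 1e-6)
  # input below the pooling minimum errors
  expect_error(ns$sdcnn_forward(m, array(0.1, c(8, 8, 3))), "too small")
})

test_that("training overfits one small batch and checkpoints at min val loss", {
  ds <- generate_sorting_dataset(8, side = 64, seed = 3)
  sub <- list(images = ds$images, onehot = ds$onehot)
  m <- build_sdcnn(conv_widths = c(4L, 8L), seed = 2)
  fit <- train_classifier(m, sub, sub, schedule = list(epochs = 6L), seed = 4)
  h <- fit$history
  # loss decreases over the first epochs (small tolerance for SGD noise)
  expect_lt(h$train_loss[5], h$train_loss[1] + 1e-8)
  expect_true(all(diff(h$train_loss[1:5]) <= 0.05))
  # checkpoint selection contract
  expect_equal(fit$checkpoint_epoch, h$epoch[which.min(h$val_loss)])
  # history carries all per-epoch fields
  expect_true(all(c("epoch", "lr", "train_loss", "train_acc", "val_loss",
                    "val_acc", "val_auc") %in% names(h)))
})

test_that("fine-tuning keeps accuracy on the same domain and is a no-op at 0 epochs", {
  ds <- generate_sorting_dataset(60, side = 64, seed = 5)
  set.seed(1)
  idx <- sample(60)
  sub <- function(i) list(images = ds$images[i],
                          onehot = ds$onehot[i, , drop = FALSE])
  m <- build_sdcnn(conv_widths = c(4L, 8L), seed = 6)
  fit <- train_classifier(m, sub(idx[1:40]), sub(idx[41:60]),
                          schedule = list(epochs = 4L), seed = 7)
  src_acc <- utils::tail(fit$history$val_acc, 1)
  # zero-epoch fine-tune returns the model unchanged
  ft0 <- fine_tune(fit$model, sub(idx[1:40]), sub(idx[41:60]),
                   schedule = list(epochs = 0L))
  expect_identical(ft0$model$params, fit$model$params)
  # short fine-tune on the same domain: no catastrophic forgetting
  ft <- fine_tune(fit$model, sub(idx[1:40]), sub(idx[41:60]),
                  schedule = list(epochs = 2L), seed = 8)
  expect_gte(utils::tail(ft$history$val_acc, 1), src_acc - 0.05)
  # fine-tune learning rates follow the two-step rule
  expect_equal(unique(ft$history$lr), 2e-4)
})

test_that("cross-validation partitions the data into disjoint covering folds", {
  ds <- generate_sorting_dataset(20, side = 64, seed = 9)
  cv <- cross_validate(ds, k = 5, schedule = list(epochs = 1L), seed = 10,
                       model_args = list(conv_widths = c(4L, 8L)))
  expect_length(cv$folds, 5L)
  sizes <- vapply(cv$folds, function(f) length(f$val_indices), integer(1))
  expect_true(all(sizes == 4L))
  all_idx <- sort(unlist(lapply(cv$folds, function(f) f$val_indices)))
  expect_equal(all_idx, 1:20)  # disjoint cover
  # same seed reproduces the same partition
  cv2 <- cross_validate(ds, k = 5, schedule = list(epochs = 1L), seed = 10,
                        model_args = list(conv_widths = c(4L, 8L)))
  expect_identical(lapply(cv$folds, `[[`, "val_indices"),
                   lapply(cv2$folds, `[[`, "val_indices"))
  expect_error(cross_validate(ds, k = 21), "folds")
  expect_true(all(is.finite(cv$summary$val_accuracy)))
})

test_that("prediction thresholds at 0.5 with ties resolving to focused", {
  m <- build_sdcnn(conv_widths = c(4L, 8L), seed = 11)
  imgs <- lapply(1:3, function(i) tiny_scene(64, 2, seed = i))
  pr <- predict_focus(m, imgs)
  expect_equal(dim(pr$probabilities), c(3L, 2L))
  expect_equal(rowSums(pr$probabilities), rep(1, 3), tolerance = 1e-6)
  expect_true(all(pr$labels %in% c("focused", "defocused")))
  expect_equal(pr$labels, ifelse(pr$probabilities[, 1] >= 0.5,
                                 "focused", "defocused"))
  # a constant-logit model puts exactly 0.5 on each class -> focused
  m0 <- m
  m0$params$dense$w[] <- 0
  m0$params$dense$b[] <- 0
  pr0 <- predict_focus(m0, imgs[1])
  expect_equal(pr0$probabilities[1, ], c(focused = 0.5, defocused = 0.5))
  expect_equal(pr0$labels[1], "focused")
})
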