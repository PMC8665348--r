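#' Build the small defocus-sorting CNN (SDCNN)
#'
#' A deliberately simple classifier built from basic layers only: a stack of
#' 3 x 3 same-padded convolution blocks (ReLU, 2 x 2 max-pool after each),
#' a global-average-pooling head in place of flattening, and a two-node
#' dense layer with softmax. One-hot convention: `[1, 0]` = focused,
#' `[0, 1]` = defocused. Thanks to the global pooling the network accepts
#' any input side large enough to survive the pooling stages.
#'
#' @param input_channels 3 (grayscale inputs are replicated to 3 channels)
#' @param conv_widths filter counts of the convolution blocks
#' @param kernel convolution kernel side (odd)
#' @param seed seed for weight initialization
#' @return object of class `sdcnn`
#' @export
build_sdcnn <- function(input_channels = 3L, conv_widths = c(32L, 64L, 128L, 256L),
                        kernel = 3L, seed = 1L) {
  stopifnot(length(conv_widths) >= 1, kernel %% 2L == 1L)
  with_seed(seed, {
    params <- list()
    cin <- input_channels
    for (i in seq_along(conv_widths)) {
      params[[paste0("conv", i)]] <- init_conv(kernel, kernel, cin, conv_widths[i])
      cin <- conv_widths[i]
    }
    params$dense <- init_dense(cin, 2L)
    structure(list(spec = list(input_channels = input_channels,
                               conv_widths = as.integer(conv_widths),
                               kernel = as.integer(kernel)),
                   params = params, train_side = NA_integer_),
              class = "sdcnn")
  })
}

#' Number of trainable parameters of a model
#' @param model an `sdcnn` or `resunet` model
#' @export
n_parameters <- function(model) {
  sum(vapply(flatten_params(model$params), length, integer(1)))
}

sdcnn_min_side <- function(model) 2L^length(model$spec$conv_widths)

sdcnn_forward <- function(model, x, keep_cache = FALSE) {
  x <- to_rgb(x)
  if (min(dim(x)[1:2]) < sdcnn_min_side(model)) {
    stop("input side ", dim(x)[1], " too small; needs at least ",
         sdcnn_min_side(model))
  }
  pad <- (model$spec$kernel - 1L) %/% 2L
  nb <- length(model$spec$conv_widths)
  cache <- list(blocks = vector("list", nb))
  for (i in seq_len(nb)) {
    p <- model$params[[paste0("conv", i)]]
    z <- nn_conv_fw(x, p$w, p$b, pad)
    a <- nn_relu_fw(z)
    # drop odd trailing row/col before pooling (floor semantics)
    d <- dim(a)
    ae <- a[seq_len(d[1] - d[1] %% 2L), seq_len(d[2] - d[2] %% 2L), , drop = FALSE]
    pl <- nn_pool_fw(ae)
    if (keep_cache) {
      cache$blocks[[i]] <- list(x = x, z = z, a_dim = d, ae_dim = dim(ae),
                                idx = pl$idx)
    }
    x <- pl$out
  }
  v <- nn_gap_fw(x)
  logits <- nn_dense_fw(v, model$params$dense$w, model$params$dense$b)
  if (keep_cache) {
    cache$feat_dim <- dim(x)
    cache$v <- v
  }
  list(logits = logits, prob = nn_softmax(logits), cache = cache)
}

sdcnn_backward <- function(model, cache, glogits) {
  grads <- list()
  db <- nn_dense_bw(cache$v, model$params$dense$w, glogits)
  grads$dense <- list(w = db$gw, b = db$gb)
  gx <- nn_gap_bw(db$gx, cache$feat_dim)
  pad <- (model$spec$kernel - 1L) %/% 2L
  for (i in rev(seq_along(cache$blocks))) {
    bl <- cache$blocks[[i]]
    p <- model$params[[paste0("conv", i)]]
    gae <- nn_pool_bw(gx, bl$idx, bl$ae_dim[1], bl$ae_dim[2])
    ga <- array(0, dim = bl$a_dim)
    ga[seq_len(bl$ae_dim[1]), seq_len(bl$ae_dim[2]), ] <- gae
    gz <- nn_relu_bw(bl$z, ga)
    cb <- nn_conv_bw(bl$x, p$w, gz, pad)
    grads[[paste0("conv", i)]] <- list(w = cb$gw, b = cb$gb)
    gx <- cb$gx
  }
  grads
}

prep_classifier_input <- function(img, side = NULL) {
  img <- to_rgb(img)
  if (!is.null(side) && !is.na(side) && dim(img)[1] != side) {
    img <- resize_bilinear(img, side)
  }
  standardize(img)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  fa <- flatten_params(a); fb <- flatten_params(b)
  for (nm in names(fa)) fa[[nm]] <- fa[[nm]] + fb[[nm]]
  unflatten_params(fa, a)
}

scale_grads <- function(g, s) {
  f <- flatten_params(g)
  for (nm in names(f)) f[[nm]] <- f[[nm]] * s
  unflatten_params(f, g)
}

eval_classifier <- function(model, images, onehot) {
  n <- length(images)
  loss <- 0
  prob <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    fw <- sdcnn_forward(model, images[[i]])
    l <- nn_softmax_ce(fw$logits, onehot[i, ])
    loss <- loss + l$loss
    prob[i, ] <- l$prob
  }
  pred <- ifelse(prob[, 1] >= 0.5, 1, 0)
  truth <- onehot[, 1]
  acc <- mean(pred == truth)
  auc <- if (length(unique(truth)) == 2) roc_auc(truth, prob[, 1])$auc else NA_real_
  list(loss = loss / n, accuracy = acc, auc = auc, prob = prob)
}

train_classifier_impl <- function(model, train, val, schedule, seed) {
  epochs <- schedule$epochs %||% 50L
  batch <- schedule$batch %||% 4L
  momentum <- schedule$momentum %||% 0.9
  n <- length(train$images)
  if (n == 0) stop("empty training set")
  if (length(unique(train$onehot[, 1])) < 2) {
    warning("training labels contain a single class")
  }
  tr_imgs <- lapply(train$images, prep_classifier_input)
  va_imgs <- lapply(val$images, prep_classifier_input)
  model$train_side <- dim(tr_imgs[[1]])[1]
  opt <- opt_init("sgd_momentum", model$params)
  history <- NULL
  best <- list(loss = Inf, params = model$params, epoch = NA_integer_)
  with_seed(seed, {
    for (epoch in 0:(epochs - 1L)) {
      lr <- lr_at_epoch(schedule, epoch)
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        gsum <- NULL
        for (i in idx) {
          fw <- sdcnn_forward(model, tr_imgs[[i]], keep_cache = TRUE)
          l <- nn_softmax_ce(fw$logits, train$onehot[i, ])
          ep_loss <- ep_loss + l$loss
          ep_correct <- ep_correct +
            ((l$prob[1] >= 0.5) == (train$onehot[i, 1] == 1))
          g <- sdcnn_backward(model, fw$cache, l$grad)
          gsum <- add_grads(gsum, g)
        }
        gsum <- scale_grads(gsum, 1 / length(idx))
        st <- opt_step(opt, model$params, gsum, lr, momentum)
        opt <- st$opt
        model$params <- st$params
      }
      ev <- eval_classifier(model, va_imgs, val$onehot)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = ep_loss / n,
        train_acc = ep_correct / n, val_loss = ev$loss,
        val_acc = ev$accuracy, val_auc = ev$auc))
      if (ev$loss < best$loss) {
        best <- list(loss = ev$loss, params = model$params, epoch = epoch)
      }
    }
  })
  model$params <- best$params
  list(model = model, history = history, checkpoint_epoch = best$epoch)
}

#' Train the sorting model
#'
#' Minimizes categorical cross-entropy with SGD + momentum 0.9, batch size
#' 4, initial learning rate 0.001 halved every five epochs. Each image is
#' standardized to mean 0 / s.d. 1 before input. The returned model is the
#' checkpoint with the lowest validation loss.
#'
#' @param model an `sdcnn` model
#' @param train,val datasets: lists with `images` (list of arrays) and
#'   `onehot` (n x 2 matrix), e.g. from [generate_sorting_dataset()]
#' @param schedule list: `epochs` (default 50), `batch` (4), `lr0` (0.001),
#'   `momentum` (0.9), `kind` ("halving")
#' @param seed seed governing shuffling
#' @return list with `model` (best checkpoint), `history` (per-epoch
#'   data.frame), `checkpoint_epoch`
#' @export
train_classifier <- function(model, train, val, schedule = list(), seed = 1L) {
  schedule$kind <- schedule$kind %||% "halving"
  train_classifier_impl(model, train, val, schedule, seed)
}

#' Fine-tune a trained sorting model on a new dataset
#'
#' Transfer learning: continues training with the reduced two-step learning
#' rate (2e-4, then 1e-4 after 25 epochs). Zero epochs returns the model
#' unchanged.
#'
#' @inheritParams train_classifier
#' @export
fine_tune <- function(model, train, val, schedule = list(), seed = 1L) {
  schedule$kind <- "finetune"
  epochs <- schedule$epochs %||% 50L
  if (epochs == 0L) {
    return(list(model = model, history = NULL, checkpoint_epoch = NA_integer_))
  }
  train_classifier_impl(model, train, val, schedule, seed)
}

#' k-fold cross-validation of the sorter
#'
#' Shuffles the dataset into k near-equal folds; each fold serves once as
#' the validation set while a fresh model is trained on the rest. Models
#' are trained for the full epoch budget and evaluated on the held-out
#' fold.
#'
#' @param dataset list with `images` and `onehot`
#' @param k number of folds (default 5)
#' @param schedule training schedule as in [train_classifier()]
#' @param seed seed governing the partition and training
#' @param model_args arguments passed to [build_sdcnn()]
#' @return list with `folds` (per-fold list: fold_id, indices, metrics) and
#'   `summary` (data.frame)
#' @export
cross_validate <- function(dataset, k = 5L, schedule = list(), seed = 1L,
                           model_args = list()) {
  n <- length(dataset$images)
  if (k > n) stop("more folds than samples")
  assign_folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    vidx <- which(assign_folds == f)
    tidx <- which(assign_folds != f)
    model <- do.call(build_sdcnn, c(model_args, list(seed = seed + f)))
    fit <- train_classifier(model,
                            list(images = dataset$images[tidx],
                                 onehot = dataset$onehot[tidx, , drop = FALSE]),
                            list(images = dataset$images[vidx],
                                 onehot = dataset$onehot[vidx, , drop = FALSE]),
                            schedule, seed = seed + 100L * f)
    hist_last <- fit$history[nrow(fit$history), ]
    folds[[f]] <- list(fold_id = f, val_indices = vidx,
                       train_metrics = list(loss = hist_last$train_loss,
                                            accuracy = hist_last$train_acc),
                       val_metrics = list(loss = hist_last$val_loss,
                                          accuracy = hist_last$val_acc,
                                          auc = hist_last$val_auc),
                       model = fit$model)
  }
  summary <- do.call(rbind, lapply(folds, function(f) {
    data.frame(fold = f$fold_id, val_accuracy = f$val_metrics$accuracy,
               val_auc = f$val_metrics$auc, val_loss = f$val_metrics$loss)
  }))
  list(folds = folds, summary = summary)
}

#' Classify images as focused or defocused
#'
#' Standardizes each image (resizing to the model's training side when one
#' is recorded and differs), runs the forward pass, and thresholds the
#' softmax at 0.5. A 0.5/0.5 tie resolves to "focused" (the first class).
#'
#' @param model trained `sdcnn`
#' @param images list of H x W x C arrays (or a single array)
#' @param resize_to side to resize inputs to before scoring; defaults to
#'   the model's training side, `NA` to disable
#' @return list with `probabilities` (n x 2 matrix, column 1 = focused) and
#'   `labels` (character)
#' @export
predict_focus <- function(model, images, resize_to = model$train_side) {
  if (is.array(images)) images <- list(images)
  n <- length(images)
  prob <- matrix(0, n, 2, dimnames = list(NULL, c("focused", "defocused")))
  for (i in seq_len(n)) {
    x <- prep_classifier_input(images[[i]], resize_to)
    prob[i, ] <- sdcnn_forward(model, x)$prob
  }
  list(probabilities = prob,
       labels = unname(ifelse(prob[, 1] >= 0.5, "focused", "defocused")))
}
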