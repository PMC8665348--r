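# Residual pre-activation blocks inside a valid-convolution UNet.
# Main path:    y1 = Conv3x3(ReLU(IN(Conv3x3(ReLU(IN(x))))))
# Shortcut:     y2 = Conv1x1(ReLU(IN(Crop(x))))      (crop 2 px per border)
# Encoder adds a 2x2 max-pool on y1 + y2; the pre-pool sum feeds the skip
# connection. All convolutions are valid, so each block shrinks the side
# by 4 and the whole depth-4 network maps side s to s - 184.

init_res_block <- function(cin, cout) {
  list(in1 = init_instnorm(cin), conv1 = init_conv(3L, 3L, cin, cout),
       in2 = init_instnorm(cout), conv2 = init_conv(3L, 3L, cout, cout),
       ins = init_instnorm(cin), convs = init_conv(1L, 1L, cin, cout))
}

res_block_fw <- function(x, p, keep_cache = FALSE) {
  n1 <- nn_instnorm_fw(x, p$in1$gamma, p$in1$beta)
  a1 <- nn_relu_fw(n1$y)
  c1 <- nn_conv_fw(a1, p$conv1$w, p$conv1$b)
  n2 <- nn_instnorm_fw(c1, p$in2$gamma, p$in2$beta)
  a2 <- nn_relu_fw(n2$y)
  y1 <- nn_conv_fw(a2, p$conv2$w, p$conv2$b)
  xc <- nn_crop_center(x, 2L)
  n3 <- nn_instnorm_fw(xc, p$ins$gamma, p$ins$beta)
  a3 <- nn_relu_fw(n3$y)
  y2 <- nn_conv_fw(a3, p$convs$w, p$convs$b)
  y <- y1 + y2
  cache <- if (keep_cache) {
    list(x_dim = dim(x), n1 = n1, a1 = a1, n2 = n2, a2 = a2, xc = xc,
         n3 = n3, a3 = a3)
  }
  list(y = y, cache = cache)
}

res_block_bw <- function(p, cache, gy) {
  g <- list()
  cb2 <- nn_conv_bw(cache$a2, p$conv2$w, gy)
  g$conv2 <- list(w = cb2$gw, b = cb2$gb)
  gn2 <- nn_relu_bw(cache$n2$y, cb2$gx)
  ib2 <- nn_instnorm_bw(cache$n2, p$in2$gamma, gn2)
  g$in2 <- list(gamma = ib2$ggamma, beta = ib2$gbeta)
  cb1 <- nn_conv_bw(cache$a1, p$conv1$w, ib2$gx)
  g$conv1 <- list(w = cb1$gw, b = cb1$gb)
  gn1 <- nn_relu_bw(cache$n1$y, cb1$gx)
  ib1 <- nn_instnorm_bw(cache$n1, p$in1$gamma, gn1)
  g$in1 <- list(gamma = ib1$ggamma, beta = ib1$gbeta)
  cbs <- nn_conv_bw(cache$a3, p$convs$w, gy)
  g$convs <- list(w = cbs$gw, b = cbs$gb)
  gn3 <- nn_relu_bw(cache$n3$y, cbs$gx)
  ib3 <- nn_instnorm_bw(cache$n3, p$ins$gamma, gn3)
  g$ins <- list(gamma = ib3$ggamma, beta = ib3$gbeta)
  gx <- ib1$gx + nn_crop_center_bw(ib3$gx, cache$x_dim, 2L)
  list(gx = gx, grads = g)
}

# plain (non-residual) block for the UNet comparison arm:
# Conv3x3 -> IN -> ReLU -> Conv3x3 -> IN -> ReLU
plain_block_fw <- function(x, p, keep_cache = FALSE) {
  c1 <- nn_conv_fw(x, p$conv1$w, p$conv1$b)
  n1 <- nn_instnorm_fw(c1, p$in1$gamma, p$in1$beta)
  a1 <- nn_relu_fw(n1$y)
  c2 <- nn_conv_fw(a1, p$conv2$w, p$conv2$b)
  n2 <- nn_instnorm_fw(c2, p$in2$gamma, p$in2$beta)
  y <- nn_relu_fw(n2$y)
  cache <- if (keep_cache) list(x = x, n1 = n1, a1 = a1, n2 = n2)
  list(y = y, cache = cache)
}

plain_block_bw <- function(p, cache, gy) {
  g <- list()
  gn2 <- nn_relu_bw(cache$n2$y, gy)
  ib2 <- nn_instnorm_bw(cache$n2, p$in2$gamma, gn2)
  g$in2 <- list(gamma = ib2$ggamma, beta = ib2$gbeta)
  cb2 <- nn_conv_bw(cache$a1, p$conv2$w, ib2$gx)
  g$conv2 <- list(w = cb2$gw, b = cb2$gb)
  gn1 <- nn_relu_bw(cache$n1$y, cb2$gx)
  ib1 <- nn_instnorm_bw(cache$n1, p$in1$gamma, gn1)
  g$in1 <- list(gamma = ib1$ggamma, beta = ib1$gbeta)
  cb1 <- nn_conv_bw(cache$x, p$conv1$w, ib1$gx)
  g$conv1 <- list(w = cb1$gw, b = cb1$gb)
  list(gx = cb1$gx, grads = g)
}

#' Spatial geometry of the valid-convolution UNet
#'
#' For a given input side, returns the output side, or `NA` if the side is
#' inadmissible (some stage would hit an odd or non-positive size). With
#' depth 4 the admissible sides are `204 + 16 m` for integer `m >= 0`
#' (572 among them), and the output side is always `input - 184`.
#'
#' @param side input side in px
#' @param depth number of down/up stages (default 4)
#' @return output side or `NA`
#' @export
resunet_output_side <- function(side, depth = 4L) {
  s <- side
  for (l in seq_len(depth)) {
    s <- s - 4L
    if (s < 2L || s %% 2L != 0L) return(NA_integer_)
    s <- s %/% 2L
  }
  s <- s - 4L  # bottleneck block
  if (s < 1L) return(NA_integer_)
  for (l in seq_len(depth)) s <- 2L * s - 4L
  as.integer(s)
}

#' Build the ResUNet reconstruction model
#'
#' A depth-4 UNet with valid 3 x 3 convolutions whose double-convolution
#' stages are replaced by pre-activation residual blocks with instance
#' normalization (see [resunet_output_side()] for the geometry: input 572
#' maps to output 388). Encoder widths double per level from `base_width`;
#' upsampling is by 2 x 2 stride-2 transpose convolutions, skip connections
#' are center-cropped and concatenated, and a final 1 x 1 linear convolution
#' maps to the output channels.
#'
#' @param base_width filters at the first level (64 for the full-size
#'   model; small values such as 8 give a desk-scale model)
#' @param depth number of resolution levels (default 4)
#' @param in_channels,out_channels image channels (3)
#' @param residual FALSE builds the plain-UNet comparison arm (same
#'   geometry, conventional conv-norm-ReLU blocks)
#' @param seed seed for weight initialization
#' @return object of class `resunet`
#' @export
build_resunet <- function(base_width = 64L, depth = 4L, in_channels = 3L,
                          out_channels = 3L, residual = TRUE, seed = 1L) {
  with_seed(seed, {
    widths <- base_width * 2L^(0:(depth - 1L))
    init_block <- function(cin, cout) {
      if (residual) init_res_block(cin, cout) else {
        list(conv1 = init_conv(3L, 3L, cin, cout), in1 = init_instnorm(cout),
             conv2 = init_conv(3L, 3L, cout, cout), in2 = init_instnorm(cout))
      }
    }
    params <- list()
    cin <- in_channels
    for (l in seq_len(depth)) {
      params[[paste0("enc", l)]] <- init_block(cin, widths[l])
      cin <- widths[l]
    }
    bw_ <- base_width * 2L^depth
    params$bottleneck <- init_block(cin, bw_)
    cin <- bw_
    for (l in rev(seq_len(depth))) {
      params[[paste0("up", l)]] <- init_conv(2L, 2L, cin, widths[l])
      params[[paste0("dec", l)]] <- init_block(2L * widths[l], widths[l])
      cin <- widths[l]
    }
    params$final <- init_conv(1L, 1L, cin, out_channels)
    # zero-init the last layer, bias at the intensity mid-point: the
    # untrained network then outputs the flat 0.5 plane and early training
    # spends its steps on structure rather than unlearning random texture
    params$final$w[] <- 0
    params$final$b <- rep(0.5, out_channels)
    structure(list(spec = list(base_width = as.integer(base_width),
                               depth = as.integer(depth),
                               in_channels = in_channels,
                               out_channels = out_channels,
                               residual = residual),
                   params = params), class = "resunet")
  })
}

resunet_forward <- function(model, x, keep_cache = FALSE) {
  x <- as_image(x)
  side <- image_side(x)
  if (is.na(resunet_output_side(side, model$spec$depth))) {
    m <- max(0, ceiling((side - 204) / 16))
    stop("input side ", side, " not admissible; nearest admissible sides: ",
         204 + 16 * max(0, m - 1), ", ", 204 + 16 * m, ", ", 204 + 16 * (m + 1))
  }
  depth <- model$spec$depth
  block_fw <- if (model$spec$residual) res_block_fw else plain_block_fw
  cache <- list(enc = vector("list", depth), dec = vector("list", depth),
                pool = vector("list", depth), tconv_x = vector("list", depth),
                skips_dim = vector("list", depth))
  skips <- vector("list", depth)
  for (l in seq_len(depth)) {
    bf <- block_fw(x, model$params[[paste0("enc", l)]], keep_cache)
    skips[[l]] <- bf$y
    pl <- nn_pool_fw(bf$y)
    if (keep_cache) {
      cache$enc[[l]] <- bf$cache
      cache$pool[[l]] <- list(idx = pl$idx, dim = dim(bf$y))
    }
    x <- pl$out
  }
  bf <- block_fw(x, model$params$bottleneck, keep_cache)
  if (keep_cache) cache$bottleneck <- bf$cache
  u <- bf$y
  for (l in rev(seq_len(depth))) {
    pu <- model$params[[paste0("up", l)]]
    if (keep_cache) cache$tconv_x[[l]] <- u
    u <- nn_tconv_fw(u, pu$w, pu$b)
    margin <- (dim(skips[[l]])[1] - dim(u)[1]) %/% 2L
    sk <- nn_crop_center(skips[[l]], margin)
    if (keep_cache) {
      cache$skips_dim[[l]] <- list(dim = dim(skips[[l]]), margin = margin)
    }
    cat_in <- array(c(sk, u), dim = c(dim(u)[1], dim(u)[2],
                                      dim(sk)[3] + dim(u)[3]))
    bf <- block_fw(cat_in, model$params[[paste0("dec", l)]], keep_cache)
    if (keep_cache) {
      cache$dec[[l]] <- bf$cache
      cache$dec[[l]]$cat_split <- dim(sk)[3]
      cache$dec[[l]]$cat_in_dim <- dim(cat_in)
    }
    u <- bf$y
  }
  if (keep_cache) cache$final_x <- u
  y <- nn_conv_fw(u, model$params$final$w, model$params$final$b)
  list(y = y, cache = cache, skips = if (keep_cache) NULL else NA)
}

resunet_backward <- function(model, cache, gy) {
  depth <- model$spec$depth
  block_bw <- if (model$spec$residual) res_block_bw else plain_block_bw
  grads <- list()
  cbf <- nn_conv_bw(cache$final_x, model$params$final$w, gy)
  grads$final <- list(w = cbf$gw, b = cbf$gb)
  gu <- cbf$gx
  gskips <- vector("list", depth)
  for (l in seq_len(depth)) {
    bb <- block_bw(model$params[[paste0("dec", l)]], cache$dec[[l]], gu)
    grads[[paste0("dec", l)]] <- bb$grads
    nsk <- cache$dec[[l]]$cat_split
    gcat <- bb$gx
    gsk <- gcat[, , seq_len(nsk), drop = FALSE]
    gup <- gcat[, , (nsk + 1):dim(gcat)[3], drop = FALSE]
    sd_ <- cache$skips_dim[[l]]
    gskips[[l]] <- nn_crop_center_bw(gsk, sd_$dim, sd_$margin)
    tb <- nn_tconv_bw(cache$tconv_x[[l]], model$params[[paste0("up", l)]]$w, gup)
    grads[[paste0("up", l)]] <- list(w = tb$gw, b = tb$gb)
    gu <- tb$gx
  }
  bb <- block_bw(model$params$bottleneck, cache$bottleneck, gu)
  grads$bottleneck <- bb$grads
  gx <- bb$gx
  for (l in rev(seq_len(depth))) {
    pc <- cache$pool[[l]]
    gpre <- nn_pool_bw(gx, pc$idx, pc$dim[1], pc$dim[2]) + gskips[[l]]
    bb <- block_bw(model$params[[paste0("enc", l)]], cache$enc[[l]], gpre)
    grads[[paste0("enc", l)]] <- bb$grads
    gx <- bb$gx
  }
  grads
}

#' Train the reconstruction model
#'
#' Optimizes the chosen loss (SSIM loss by default, see [ssim_loss()];
#' alternatives `"l1"` and `"combinatory"`) with Nadam at its customary
#' default parameters, batch size 2. Inputs are the defocused images
#' mirror-padded by 92 px per border ([symmetric_pad()]) so the valid-
#' convolution network returns an image of the original size; targets are
#' the focused images in `[0, 1]` (no standardization — instance
#' normalization inside every block preserves each image's own statistics).
#' The returned model is the checkpoint with the highest validation SSIM.
#'
#' @param model a `resunet` model
#' @param pairs list of pairs (`defocused`, `focused`), e.g. from
#'   [generate_reconstruction_dataset()]
#' @param schedule list: `epochs` (default 60; 40 is used for small
#'   per-condition datasets), `batch` (2), `lr` (0.001), `loss` ("ssim")
#' @param val_pairs held-out pairs for checkpoint selection; when NULL, a
#'   fifth of `pairs` is split off
#' @param seed seed governing shuffling and the split
#' @return list with `model`, `history`, `checkpoint_epoch`
#' @export
train_reconstructor <- function(model, pairs, schedule = list(),
                                val_pairs = NULL, seed = 1L) {
  if (length(pairs) == 0) stop("empty training pairs")
  epochs <- schedule$epochs %||% 60L
  batch <- schedule$batch %||% 2L
  lr <- schedule$lr %||% 0.001
  loss_kind <- schedule$loss %||% "ssim"
  if (is.null(val_pairs)) {
    nval <- max(1L, length(pairs) %/% 5L)
    vidx <- with_seed(seed, sample.int(length(pairs), nval))
    val_pairs <- pairs[vidx]
    pairs <- pairs[-vidx]
  }
  target_side <- image_side(pairs[[1]]$focused)
  input_side <- target_side + 184L
  if (is.na(resunet_output_side(input_side, model$spec$depth))) {
    stop("pair side ", target_side, " incompatible with the network geometry")
  }
  prep <- function(p) list(x = symmetric_pad(p$defocused, input_side),
                           y = p$focused)
  tr <- lapply(pairs, prep)
  va <- lapply(val_pairs, prep)
  opt <- opt_init("nadam", model$params)
  history <- NULL
  best <- list(ssim = -Inf, params = model$params, epoch = NA_integer_)
  n <- length(tr)
  with_seed(seed + 1L, {
    for (epoch in 0:(epochs - 1L)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        gsum <- NULL
        for (i in idx) {
          fw <- resunet_forward(model, tr[[i]]$x, keep_cache = TRUE)
          lg <- recon_loss_grad(tr[[i]]$y, fw$y, loss_kind)
          ep_loss <- ep_loss + lg$loss
          g <- resunet_backward(model, fw$cache, lg$grad)
          gsum <- add_grads(gsum, g)
        }
        gsum <- scale_grads(gsum, 1 / length(idx))
        st <- opt_step(opt, model$params, gsum, lr)
        opt <- st$opt
        model$params <- st$params
      }
      val_ssim <- mean(vapply(va, function(p) {
        ssim(clamp01(resunet_forward(model, p$x)$y), p$y)
      }, numeric(1)))
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss / n,
                                           val_ssim = val_ssim))
      if (val_ssim > best$ssim) {
        best <- list(ssim = val_ssim, params = model$params, epoch = epoch)
      }
    }
  })
  model$params <- best$params
  list(model = model, history = history, checkpoint_epoch = best$epoch)
}

#' Reconstruct a defocused image at full frame
#'
#' A square image whose mirror-padded side (side + 184) is admissible for
#' the network — 388 in the standard workflow — is restored in a single
#' forward pass; larger frames are processed with the overlap-tile scheme
#' ([tile_and_restitch()]) over 572-px contexts, so the output always
#' matches the input size. Output intensities are clipped to `[0, 1]`.
#'
#' @param model trained `resunet`
#' @param img H x W x 3 array
#' @return reconstructed array of the same shape
#' @export
reconstruct_image <- function(model, img) {
  img <- as_image(img)
  d <- dim(img)
  f <- function(ctx) resunet_forward(model, ctx)$y
  single <- d[1] == d[2] &&
    !is.na(resunet_output_side(d[1] + 184L, model$spec$depth))
  out <- if (single) {
    f(symmetric_pad(img, d[1] + 184L))
  } else if (min(d[1:2]) >= 388L) {
    tile_and_restitch(img, f, model_in = 572L, model_out = 388L)
  } else {
    stop("image side below the 388 px minimum for tiled reconstruction ",
         "and not directly admissible")
  }
  clamp01(out)
}
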