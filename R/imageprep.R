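#' Center crop
#'
#' Crops a `side` x `side` region from the image center. With an odd
#' remainder the crop is biased toward the top-left: the row/column offset is
#' `floor((H - side) / 2)` (0-based).
#'
#' @param img H x W x C array
#' @param side crop side in px, `side <= min(H, W)`
#' @return side x side x C array
#' @export
center_crop <- function(img, side) {
  img <- as_image(img)
  d <- dim(img)
  if (side > min(d[1:2])) stop("crop side ", side, " exceeds image size")
  r0 <- (d[1] - side) %/% 2
  c0 <- (d[2] - side) %/% 2
  img[(r0 + 1):(r0 + side), (c0 + 1):(c0 + side), , drop = FALSE]
}

#' Bilinear resize to a square side
#'
#' Resamples with bilinear interpolation under the half-pixel-center
#' convention: output pixel i (0-based) samples source coordinate
#' `(i + 0.5) * H / side - 0.5`, clamped to the image. Constant images map to
#' the same constant and output values stay within the input range.
#'
#' @param img H x W x C array
#' @param side output side in px
#' @return side x side x C array
#' @export
resize_bilinear <- function(img, side) {
  img <- as_image(img)
  d <- dim(img)
  wmat <- function(n_in, n_out) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    s <- pmin(pmax(s, 0), n_in - 1)
    lo <- floor(s)
    fr <- s - lo
    hi <- pmin(lo + 1, n_in - 1)
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), lo + 1)] <- A[cbind(seq_len(n_out), lo + 1)] + (1 - fr)
    A[cbind(seq_len(n_out), hi + 1)] <- A[cbind(seq_len(n_out), hi + 1)] + fr
    A
  }
  Ar <- wmat(d[1], side)
  Ac <- wmat(d[2], side)
  out <- array(0, dim = c(side, side, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- Ar %*% img[, , ch] %*% t(Ac)
  out
}

#' Per-image standardization
#'
#' Rescales an image to zero mean and unit spread over all pixels and
#' channels jointly: `(img - mean) / max(sd, 1 / sqrt(N))`, with the
#' population standard deviation and `N` the total element count. The
#' denominator floor makes near-constant images map to (near) zeros instead
#' of amplified noise.
#'
#' @param img H x W x C array
#' @return array of the same shape, mean 0
#' @export
standardize <- function(img) {
  img <- as_image(img)
  n <- length(img)
  m <- mean(img)
  s <- sqrt(mean((img - m)^2))
  (img - m) / max(s, 1 / sqrt(n))
}

#' 3 x 3 augmentation tiling for the sorting task
#'
#' Splits a 1608 x 1608 frame into the 9 non-overlapping 536 x 536 tiles
#' that exactly partition it (row-major order).
#'
#' @param img 1608 x 1608 x C array
#' @return list of 9 tiles
#' @export
grid_crop_sorting <- function(img) {
  img <- as_image(img)
  if (image_side(img) != 1608L) stop("sorting grid crop expects a 1608 x 1608 image")
  tiles <- vector("list", 9L)
  k <- 1L
  for (i in 0:2) {
    for (j in 0:2) {
      tiles[[k]] <- img[(i * 536 + 1):((i + 1) * 536),
                        (j * 536 + 1):((j + 1) * 536), , drop = FALSE]
      k <- k + 1L
    }
  }
  tiles
}

#' 4 x 4 augmentation tiling for the reconstruction task
#'
#' Cuts 16 tiles of 388 x 388 from a 1608 x 1608 frame on a near-uniform
#' 4 x 4 grid with top-left offsets {0, 406, 813, 1220} per axis (row-major
#' order). Adjacent tiles overlap slightly; the last tile sits flush with
#' the frame edge and every source pixel is covered.
#'
#' @param img 1608 x 1608 x C array
#' @return list of 16 tiles of 388 x 388
#' @export
grid_crop_reconstruction <- function(img) {
  img <- as_image(img)
  if (image_side(img) != 1608L) stop("reconstruction grid crop expects a 1608 x 1608 image")
  offs <- c(0L, 406L, 813L, 1220L)
  tiles <- vector("list", 16L)
  k <- 1L
  for (i in offs) {
    for (j in offs) {
      tiles[[k]] <- img[(i + 1):(i + 388), (j + 1):(j + 388), , drop = FALSE]
      k <- k + 1L
    }
  }
  tiles
}

reflect_index <- function(n, pad) {
  if (pad > n - 1) stop("reflection padding ", pad, " too large for size ", n)
  c(rev(seq_len(pad)) + 1L, seq_len(n), n - seq_len(pad))
}

#' Mirror-pad a square image for valid-convolution networks
#'
#' Pads `(target_side - side) / 2` pixels on every border by mirror
#' reflection about the edge, excluding the edge pixel itself from the
#' mirror (a row `[a, b, c]` padded by 2 becomes `[c, b, a, b, c, b, a]`).
#' The central region of the result equals the input.
#'
#' @param img square H x H x C array
#' @param target_side output side; difference to the input side must be even
#' @return target_side x target_side x C array
#' @export
symmetric_pad <- function(img, target_side) {
  img <- as_image(img)
  side <- image_side(img)
  if (target_side < side) stop("target side smaller than image")
  if ((target_side - side) %% 2L != 0L) stop("pad difference must be even")
  pad <- (target_side - side) %/% 2L
  if (pad == 0L) return(img)
  idx <- reflect_index(side, pad)
  img[idx, idx, , drop = FALSE]
}

#' Overlap-tile inference over a large image
#'
#' Covers an image of arbitrary size (each side >= `model_out`) with
#' `model_out`-sized output tiles, computing each from a `model_in`-sized
#' mirror-padded context window, and reassembles them into an output of the
#' input's size. Tiles are placed without blending; the last tile in each
#' row/column is flush with the image edge, and where tiles overlap the
#' later tile wins.
#'
#' @param img H x W x C array, H and W >= `model_out`
#' @param f function mapping a model_in x model_in x C array to a
#'   model_out x model_out x C array
#' @param model_in context window side (default 572)
#' @param model_out output tile side (default 388)
#' @return array of the same spatial size as `img`
#' @export
tile_and_restitch <- function(img, f, model_in = 572L, model_out = 388L) {
  img <- as_image(img)
  d <- dim(img)
  if (min(d[1:2]) < model_out) stop("image smaller than the output tile")
  pad <- (model_in - model_out) %/% 2L
  ridx <- reflect_index(d[1], pad)
  cidx <- reflect_index(d[2], pad)
  padded <- img[ridx, cidx, , drop = FALSE]
  offsets <- function(n) {
    o <- seq(0L, n - model_out, by = model_out)
    unique(c(o, n - model_out))
  }
  out <- array(0, dim = d)
  for (r in offsets(d[1])) {
    for (cc in offsets(d[2])) {
      ctx <- padded[(r + 1):(r + model_in), (cc + 1):(cc + model_in), , drop = FALSE]
      y <- f(ctx)
      stopifnot(dim(y)[1] == model_out, dim(y)[2] == model_out)
      out[(r + 1):(r + model_out), (cc + 1):(cc + model_out), ] <- y
    }
  }
  out
}
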