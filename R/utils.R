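#' @useDynLib refocus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporarily fixed RNG state
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the state afterwards so library calls never perturb user code.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Coerce to an H x W x C image array
#'
#' Images throughout the package are numeric arrays with dimensions
#' (height, width, channels), values in `[0, 1]` and 1 or 3 channels.
#' @param x matrix or 3-d array
#' @return 3-d numeric array
#' @export
as_image <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("image must be an H x W x C array")
  if (!dim(x)[3] %in% c(1L, 3L)) stop("image must have 1 or 3 channels")
  if (!all(is.finite(x))) stop("image contains non-finite values")
  x
}

#' Replicate a grayscale image to three channels
#' @keywords internal
to_rgb <- function(img) {
  img <- as_image(img)
  if (dim(img)[3] == 3L) return(img)
  array(img, dim = c(dim(img)[1:2], 3L))
}

image_side <- function(img) {
  d <- dim(img)
  if (d[1] != d[2]) stop("operation requires a square image")
  d[1]
}
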