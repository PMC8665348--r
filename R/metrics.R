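#' SSIM parameters
#'
#' Standard constants of the structural-similarity index: an 11 x 11
#' Gaussian window with sigma 1.5 and stability constants k1 = 0.01,
#' k2 = 0.03 at dynamic range 1 (images in `[0, 1]`).
#' @export
ssim_params <- function(window = 11L, window_sigma = 1.5, k1 = 0.01,
                        k2 = 0.03, dynamic_range = 1) {
  stopifnot(window %% 2L == 1L, k1 > 0, k2 > 0)
  list(window = as.integer(window), window_sigma = window_sigma, k1 = k1,
       k2 = k2, dynamic_range = dynamic_range)
}

ssim_window <- function(params) {
  r <- (params$window - 1L) %/% 2L
  k <- exp(-0.5 * ((-r):r / params$window_sigma)^2)
  k / sum(k)
}

# Local SSIM statistics on the valid interior (no padding), per channel.
ssim_components <- function(a, b, params) {
  k <- ssim_window(params)
  C1 <- (params$k1 * params$dynamic_range)^2
  C2 <- (params$k2 * params$dynamic_range)^2
  F <- function(x) cpp_sepfilter(x, k, k, 0L)
  mu_a <- F(a); mu_b <- F(b)
  s_aa <- F(a * a) - mu_a^2
  s_bb <- F(b * b) - mu_b^2
  s_ab <- F(a * b) - mu_a * mu_b
  A1 <- 2 * mu_a * mu_b + C1
  A2 <- 2 * s_ab + C2
  B1 <- mu_a^2 + mu_b^2 + C1
  B2 <- s_aa + s_bb + C2
  list(mu_a = mu_a, mu_b = mu_b, s_aa = s_aa, s_bb = s_bb, s_ab = s_ab,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, S = (A1 * A2) / (B1 * B2), k = k)
}

#' Structural similarity index
#'
#' Mean of the local windowed SSIM map over the valid interior, channels
#' averaged. Symmetric in its arguments; `ssim(a, a) == 1`; values lie in
#' `[-1, 1]`.
#'
#' @param a,b images of equal shape (H x W x C or matrices), each side at
#'   least the window size
#' @param params [ssim_params()]
#' @return scalar SSIM
#' @export
ssim <- function(a, b, params = ssim_params()) {
  a <- as_image(a); b <- as_image(b)
  if (!all(dim(a) == dim(b))) stop("ssim: shape mismatch")
  if (min(dim(a)[1:2]) < params$window) stop("image smaller than SSIM window")
  mean(ssim_components(a, b, params)$S)
}

# d mean(SSIM) / d a for fixed b, same shape as a. The adjoint of the
# valid-mode window filtering is full-mode filtering of the pixelwise
# partial derivatives.
ssim_grad <- function(a, b, params = ssim_params()) {
  cs <- ssim_components(a, b, params)
  N <- length(cs$S)
  Ffull <- function(x) cpp_sepfilter(x, cs$k, cs$k, 1L)
  denom <- cs$B1 * cs$B2
  dS_dmu <- 2 * cs$mu_b * cs$A2 / denom - 2 * cs$mu_a * cs$S / cs$B1
  dS_dsaa <- -cs$S / cs$B2
  dS_dsab <- 2 * cs$A1 / denom
  Gmu <- dS_dmu / N
  Gv <- dS_dsaa / N
  Gc <- dS_dsab / N
  Ffull(Gmu) + 2 * a * Ffull(Gv) - 2 * Ffull(Gv * cs$mu_a) +
    b * Ffull(Gc) - Ffull(Gc * cs$mu_b)
}

#' SSIM loss: `1 - SSIM(y_true, y_pred)`
#' @param y_true,y_pred images of equal shape
#' @param params [ssim_params()]
#' @return scalar in `[0, 2]`
#' @export
ssim_loss <- function(y_true, y_pred, params = ssim_params()) {
  1 - ssim(y_true, y_pred, params)
}

#' Mean absolute error
#' @param a,b equal-shape arrays
#' @export
mae <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mae: shape mismatch")
  mean(abs(a - b))
}

#' L1 and combinatory reconstruction losses
#'
#' The combinatory loss is `L1 + 100 * SSIM_loss`; the factor 100 balances
#' the two terms.
#'
#' @param y_true,y_pred images of equal shape
#' @param params [ssim_params()]
#' @return list with `l1` and `combinatory`
#' @export
l1_and_combinatory_loss <- function(y_true, y_pred, params = ssim_params()) {
  l1 <- mae(y_true, y_pred)
  list(l1 = l1, combinatory = l1 + 100 * ssim_loss(y_true, y_pred, params))
}

# loss value + gradient wrt y_pred, for reconstruction training
recon_loss_grad <- function(y_true, y_pred, loss = c("ssim", "l1", "combinatory"),
                            params = ssim_params()) {
  loss <- match.arg(loss)
  if (loss == "ssim") {
    return(list(loss = 1 - ssim(y_true, y_pred, params),
                grad = -ssim_grad(y_pred, y_true, params)))
  }
  gl1 <- sign(y_pred - y_true) / length(y_true)
  l1 <- mean(abs(y_pred - y_true))
  if (loss == "l1") return(list(loss = l1, grad = gl1))
  list(loss = l1 + 100 * (1 - ssim(y_true, y_pred, params)),
       grad = gl1 - 100 * ssim_grad(y_pred, y_true, params))
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score thresholds; the AUC is the trapezoidal area,
#' which equals the probability that a random positive outranks a random
#' negative with ties counted one half (the Mann-Whitney statistic).
#'
#' @param labels binary vector (1/TRUE = positive)
#' @param scores real-valued scores, higher = more positive
#' @return object of class `roc_curve`: list with `thresholds`, `fpr`,
#'   `tpr`, `auc`
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("roc_auc needs both classes present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  # cumulative counts at each distinct threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l == 1)[keep]
  fp <- cumsum(l == 0)[keep]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, s[keep]), fpr = fpr, tpr = tpr,
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", length(x$fpr), "points, AUC =",
      format(x$auc, digits = 4), "\n")
  invisible(x)
}

#' Accuracy and confusion matrix
#'
#' Positive = focused, negative = defocused.
#'
#' @param labels true labels ("focused"/"defocused", or 1/0)
#' @param predictions predicted labels, same encoding
#' @return list with `accuracy` and `confusion` (tp, fp, tn, fn)
#' @export
accuracy_confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) stop("length mismatch")
  enc <- function(x) {
    if (is.character(x) || is.factor(x)) as.numeric(as.character(x) == "focused")
    else as.numeric(x)
  }
  y <- enc(labels)
  p <- enc(predictions)
  conf <- list(tp = sum(y == 1 & p == 1), fp = sum(y == 0 & p == 1),
               tn = sum(y == 0 & p == 0), fn = sum(y == 1 & p == 0))
  list(accuracy = (conf$tp + conf$tn) / length(y), confusion = conf)
}

#' Grayscale intensity profile along a segment
#'
#' Converts to grayscale (channel mean) and samples intensities along the
#' straight segment from `p_start` to `p_end` at unit-pixel spacing with
#' bilinear interpolation. Points are `(row, col)` in 1-based pixel
#' coordinates; the profile has `round(length) + 1` samples.
#'
#' @param img H x W x C array
#' @param p_start,p_end numeric length-2 vectors (row, col)
#' @return numeric vector of intensities
#' @export
intensity_profile <- function(img, p_start, p_end) {
  img <- as_image(img)
  d <- dim(img)
  gray <- if (d[3] == 1L) img[, , 1] else (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  chk <- function(p) {
    if (p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2]) {
      stop("profile endpoint outside image")
    }
  }
  chk(p_start); chk(p_end)
  len <- sqrt(sum((p_end - p_start)^2))
  n <- round(len) + 1
  t <- if (n == 1) 0 else seq(0, 1, length.out = n)
  rr <- p_start[1] + t * (p_end[1] - p_start[1])
  cc <- p_start[2] + t * (p_end[2] - p_start[2])
  r0 <- pmin(floor(rr), d[1] - 1); c0 <- pmin(floor(cc), d[2] - 1)
  fr <- rr - r0; fc <- cc - c0
  gray[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    gray[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    gray[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    gray[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' AUC of a sorter asked to tell focused images from a comparison set
#'
#' Scores both sets with a trained sorting model (probability of being
#' focused) and reports the AUC with the focused set as positives. Applied
#' to the reconstructed counterparts of defocused images this measures how
#' well reconstructions fool the sorter: authentic reconstructions pull the
#' AUC toward 0.5.
#'
#' @param sorter a trained sdcnn model
#' @param focused_set,comparison_set lists of images
#' @return scalar AUC
#' @export
cheat_auc <- function(sorter, focused_set, comparison_set) {
  if (length(focused_set) == 0 || length(comparison_set) == 0) {
    stop("cheat_auc: empty image set")
  }
  sf <- predict_focus(sorter, focused_set)$probabilities[, 1]
  sc <- predict_focus(sorter, comparison_set)$probabilities[, 1]
  roc_auc(c(rep(1, length(sf)), rep(0, length(sc))), c(sf, sc))$auc
}
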