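# Shared test helpers: independent oracles and small fixture builders.

# central-difference numerical gradient of scalar-valued f at x (vector in)
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# 4-connected component count of a logical matrix (flood fill; oracle for
# counting rendered cells)
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nrow(mask) + 1L
      cc <- (p - 1L) %/% nrow(mask) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 >= 1 && r2 <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask)) {
          q <- r2 + (c2 - 1L) * nrow(mask)
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  nxt
}

# brute-force AUC: probability a random positive outranks a random negative,
# ties counted one half
pairwise_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg) s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# variance of the Laplacian: classic no-reference sharpness score
var_laplacian <- function(img) {
  g <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  n <- nrow(g)
  lap <- 4 * g[2:(n - 1), 2:(n - 1)] -
    g[1:(n - 2), 2:(n - 1)] - g[3:n, 2:(n - 1)] -
    g[2:(n - 1), 1:(n - 2)] - g[2:(n - 1), 3:n]
  stats::var(as.vector(lap))
}

tiny_scene <- function(side = 96, n_cells = 4, seed = 1, noise_sd = 0.02) {
  render_focused_scene(scene_params(
    side = side, n_cells = n_cells,
    cell_radius_range = c(8, 16) * min(1, side / 134),
    noise_sd = noise_sd, seed = seed))
}
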