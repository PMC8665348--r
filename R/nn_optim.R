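# Optimizers operate on a flat named list of numeric arrays (the model
# parameters) and a congruent list of gradients. States are kept in plain
# lists so checkpoints remain serializable.

flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    full <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], full))
    } else {
      out[[full]] <- p[[nm]]
    }
  }
  out
}

unflatten_params <- function(flat, template) {
  assign_into <- function(p, prefix = "") {
    for (nm in names(p)) {
      full <- if (prefix == "") nm else paste0(prefix, ".", nm)
      if (is.list(p[[nm]])) {
        p[[nm]] <- assign_into(p[[nm]], full)
      } else {
        p[[nm]] <- flat[[full]]
      }
    }
    p
  }
  assign_into(template)
}

opt_init <- function(kind = c("sgd_momentum", "nadam"), params) {
  kind <- match.arg(kind)
  flat <- flatten_params(params)
  zeros <- lapply(flat, function(x) x * 0)
  list(kind = kind, v = zeros, m = zeros, t = 0L)
}

# SGD with classical momentum: v <- mu v - lr g ; w <- w + v
# Nadam (Nesterov Adam) with the customary defaults
# beta1 = 0.9, beta2 = 0.999, eps = 1e-7.
opt_step <- function(opt, params, grads, lr, momentum = 0.9) {
  flat <- flatten_params(params)
  gflat <- flatten_params(grads)
  if (opt$kind == "sgd_momentum") {
    for (nm in names(flat)) {
      g <- gflat[[nm]] %||% 0
      opt$v[[nm]] <- momentum * opt$v[[nm]] - lr * g
      flat[[nm]] <- flat[[nm]] + opt$v[[nm]]
    }
  } else {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
    opt$t <- opt$t + 1L
    t <- opt$t
    for (nm in names(flat)) {
      g <- gflat[[nm]] %||% 0
      opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
      opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
      mhat <- opt$m[[nm]] / (1 - b1^t)
      vhat <- opt$v[[nm]] / (1 - b2^t)
      upd <- (b1 * mhat + (1 - b1) * g / (1 - b1^t)) / (sqrt(vhat) + eps)
      flat[[nm]] <- flat[[nm]] - lr * upd
    }
  }
  list(opt = opt, params = unflatten_params(flat, params))
}

#' Learning rate at a given epoch
#'
#' The training schedule halves the learning rate every five epochs starting
#' from `lr0` (`lr0 * 0.5^floor(epoch / 5)`, epochs 0-based). The
#' fine-tuning rule used for transfer learning is a two-step schedule:
#' 2e-4 for the first 25 epochs, 1e-4 afterwards.
#'
#' @param schedule a list with `kind` ("halving" or "finetune") and, for
#'   halving, `lr0` (default 0.001)
#' @param epoch 0-based epoch index
#' @return learning rate
#' @export
lr_at_epoch <- function(schedule, epoch) {
  stopifnot(epoch >= 0)
  kind <- schedule$kind %||% "halving"
  if (kind == "finetune") {
    return(if (epoch < 25) 2e-4 else 1e-4)
  }
  lr0 <- schedule$lr0 %||% 0.001
  lr0 * 0.5^(epoch %/% 5)
}
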