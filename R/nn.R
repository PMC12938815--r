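## Minimal 3-D CNN engine: conv3d ("same" padding, stride 1, via the
## compiled im2col kernels), channelwise batch norm, ReLU, temporal average
## pooling, temporal crop; Adam; BCE-on-logits and 1-SSIM losses with
## analytic gradients. Tensors are R arrays (T, H, W, C); a batch is a list
## of such arrays (batch statistics pool across the whole batch).

layer_conv <- function(kt, kh, kw, cin, cout, bias = TRUE, seed = 1L) {
  fan_in <- kt * kh * kw * cin
  w <- with_seed(seed, array(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                             c(kt, kh, kw, cin, cout)))
  list(type = "conv", w = w, b = if (bias) numeric(cout) else NULL)
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c),
       momentum = momentum, eps = eps)
}

layer_relu <- function() list(type = "relu")
layer_pool_t <- function(factor) list(type = "pool_t", factor = as.integer(factor))
layer_crop_t <- function(keep) list(type = "crop_t", keep = as.integer(keep))

## reshape (T,H,W,C) -> (voxels, C) without copy semantics surprises
as_vox_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

nn_forward <- function(net, xs, training = FALSE, frozen = character(0)) {
  layers <- net$layers
  blocks <- net$blocks
  caches <- if (training) vector("list", length(layers)) else NULL
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    froz <- blocks[li] %in% frozen
    if (ly$type == "conv") {
      if (training) caches[[li]] <- list(x = xs)
      xs <- lapply(xs, function(x)
        conv3d_fwd(x, dim(x), ly$w, dim(ly$w), ly$b))
    } else if (ly$type == "bn") {
      use_batch <- training && !froz
      if (use_batch) {
        nv <- 0; s1 <- 0; s2 <- 0
        for (x in xs) {
          m <- as_vox_mat(x)
          s1 <- s1 + colSums(m); s2 <- s2 + colSums(m^2); nv <- nv + nrow(m)
        }
        mu <- s1 / nv
        va <- pmax(s2 / nv - mu^2, 0)
        layers[[li]]$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
        layers[[li]]$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * va
      } else {
        mu <- ly$run_mean; va <- ly$run_var; nv <- NA
      }
      invstd <- 1 / sqrt(va + ly$eps)
      xhat <- lapply(xs, function(x) {
        d <- dim(x); m <- as_vox_mat(x)
        m <- sweep(m, 2, mu, `-`)
        m <- sweep(m, 2, invstd, `*`)
        dim(m) <- d; m
      })
      if (training) caches[[li]] <- list(xhat = xhat, invstd = invstd,
                                         nvox = nv, batch_stats = use_batch)
      xs <- lapply(xhat, function(h) {
        d <- dim(h); m <- as_vox_mat(h)
        m <- sweep(m, 2, ly$gamma, `*`)
        m <- sweep(m, 2, ly$beta, `+`)
        dim(m) <- d; m
      })
    } else if (ly$type == "relu") {
      if (training) caches[[li]] <- list(x = xs)
      xs <- lapply(xs, function(x) pmax(x, 0))
    } else if (ly$type == "pool_t") {
      if (training) caches[[li]] <- list(dims = lapply(xs, dim))
      xs <- lapply(xs, function(x) {
        d <- dim(x); p <- ly$factor
        dim(x) <- c(p, d[1] / p, d[2] * d[3] * d[4])
        y <- colMeans(x)              # average over the pooling window
        dim(y) <- c(d[1] / p, d[2], d[3], d[4])
        y
      })
    } else if (ly$type == "crop_t") {
      if (training) caches[[li]] <- list(dims = lapply(xs, dim))
      xs <- lapply(xs, function(x) x[seq_len(ly$keep), , , , drop = FALSE])
    } else if (ly$type == "sigmoid_bridge") {
      xs <- lapply(xs, sigmoid)
      if (training) caches[[li]] <- list(y = xs)
    } else stop("unknown layer type ", ly$type)
  }
  list(out = xs, caches = caches, layers = layers)
}

nn_backward <- function(net, caches, dys, frozen = character(0)) {
  layers <- net$layers
  blocks <- net$blocks
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    froz <- blocks[li] %in% frozen
    if (ly$type == "conv") {
      xsin <- caches[[li]]$x
      need_dx <- li > 1L
      dw <- 0; db <- 0
      nds <- vector("list", length(dys))
      for (i in seq_along(dys)) {
        bw <- conv3d_bwd(xsin[[i]], dim(xsin[[i]]), ly$w, dim(ly$w),
                         dys[[i]], need_dx, !is.null(ly$b))
        if (!froz) {
          dw <- dw + bw$dw
          if (!is.null(ly$b)) db <- db + bw$db
        }
        if (need_dx) nds[[i]] <- bw$dx
      }
      if (!froz) grads[[li]] <- list(w = dw, b = if (!is.null(ly$b)) db)
      dys <- nds
    } else if (ly$type == "bn") {
      ca <- caches[[li]]
      xhat <- ca$xhat; invstd <- ca$invstd
      dgamma <- 0; dbeta <- 0
      sum_dxhat <- 0; sum_dxhat_xhat <- 0
      dxh <- vector("list", length(dys))
      for (i in seq_along(dys)) {
        d <- dim(dys[[i]])
        dm <- as_vox_mat(dys[[i]]); hm <- as_vox_mat(xhat[[i]])
        dgamma <- dgamma + colSums(dm * hm)
        dbeta <- dbeta + colSums(dm)
        dh <- sweep(dm, 2, ly$gamma, `*`)
        sum_dxhat <- sum_dxhat + colSums(dh)
        sum_dxhat_xhat <- sum_dxhat_xhat + colSums(dh * hm)
        dxh[[i]] <- dh
      }
      if (!froz) grads[[li]] <- list(gamma = dgamma, beta = dbeta)
      if (isTRUE(ca$batch_stats)) {
        nv <- ca$nvox
        for (i in seq_along(dys)) {
          hm <- as_vox_mat(xhat[[i]])
          dm <- dxh[[i]] - matrix(sum_dxhat / nv, nrow(dxh[[i]]),
                                  length(invstd), byrow = TRUE) -
            hm * matrix(sum_dxhat_xhat / nv, nrow(hm), length(invstd), byrow = TRUE)
          dm <- sweep(dm, 2, invstd, `*`)
          d <- dim(xhat[[i]]); dim(dm) <- d
          dys[[i]] <- dm
        }
      } else {
        for (i in seq_along(dys)) {
          dm <- sweep(dxh[[i]], 2, invstd, `*`)
          dim(dm) <- dim(xhat[[i]])
          dys[[i]] <- dm
        }
      }
    } else if (ly$type == "relu") {
      xsin <- caches[[li]]$x
      for (i in seq_along(dys)) dys[[i]] <- dys[[i]] * (xsin[[i]] > 0)
    } else if (ly$type == "pool_t") {
      dims <- caches[[li]]$dims
      for (i in seq_along(dys)) {
        d0 <- dims[[i]]; p <- ly$factor
        dy <- dys[[i]]
        up <- array(0, c(p, d0[1] / p, d0[2], d0[3], d0[4]))
        for (j in seq_len(p)) up[j, , , , ] <- dy / p
        dim(up) <- d0
        dys[[i]] <- up
      }
    } else if (ly$type == "crop_t") {
      dims <- caches[[li]]$dims
      for (i in seq_along(dys)) {
        d0 <- dims[[i]]
        full <- array(0, d0)
        full[seq_len(ly$keep), , , ] <- dys[[i]]
        dys[[i]] <- full
      }
    } else if (ly$type == "sigmoid_bridge") {
      ys <- caches[[li]]$y
      for (i in seq_along(dys)) dys[[i]] <- dys[[i]] * ys[[i]] * (1 - ys[[i]])
    }
  }
  grads
}

## ---- losses on logits -------------------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

## stable per-voxel mean BCE from logits; returns loss and d(loss)/d(logits)
bce_logits_loss <- function(z, target) {
  n <- length(z)
  loss <- sum(pmax(z, 0) - z * target + log1p(exp(-abs(z)))) / n
  grad <- (sigmoid(z) - target) / n
  list(loss = loss, grad = grad)
}

## 1 - SSIM loss between sigmoid(logits) (a (1,H,W,1) array) and a target
## image matrix; gradient wrt the logits.
ssim_logits_loss <- function(z, target, settings) {
  d <- dim(z)
  img <- sigmoid(z)
  m <- matrix(img, d[2], d[3])
  s <- ssim_with_grad(m, as.matrix(target), settings)
  dimg <- -s$grad                 # d(1 - ssim)/d(pred)
  dz <- dimg * m * (1 - m)
  list(loss = 1 - s$value, grad = array(dz, d), value = s$value)
}

## ---- Adam -------------------------------------------------------------------

adam_init <- function() new.env(parent = emptyenv())

adam_step <- function(net, grads, opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- (opt$t %||% 0) + 1
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (li in seq_along(grads)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      key <- paste0("l", li, "_", nm)
      m <- opt[[paste0(key, "_m")]] %||% 0
      v <- opt[[paste0(key, "_v")]] %||% 0
      m <- beta1 * m + (1 - beta1) * g[[nm]]
      v <- beta2 * v + (1 - beta2) * g[[nm]]^2
      opt[[paste0(key, "_m")]] <- m
      opt[[paste0(key, "_v")]] <- v
      upd <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
      net$layers[[li]][[nm]] <- net$layers[[li]][[nm]] - upd
    }
  }
  net
}

## ---- generic training loop --------------------------------------------------

## prepares an input array with a trailing channel axis
with_channel <- function(x) {
  x <- unclass(x)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Training configuration
#'
#' Adam settings and the early-stopping protocol shared by all training
#' stages: learning rate `1e-4` for pretraining and `0.5e-4` for the
#' alternating refinement, batch size 2, epoch count chosen adaptively by
#' early stopping on a monitored validation metric (F1 for the spike
#' decoder, SSIM for image decoders).
#'
#' @param lr Pretraining learning rate.
#' @param lr_refine Refinement learning rate.
#' @param batch_size Mini-batch size (default 2).
#' @param max_epochs Epoch cap per training phase.
#' @param patience Early-stopping patience in epochs.
#' @param min_delta Minimum metric improvement counted as progress.
#' @param rounds Alternating-refinement rounds (default 3).
#' @param refine_epochs Epoch cap for each refinement phase.
#' @param seed Seed for shuffling and any stochastic choice.
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, lr_refine = 0.5e-4, batch_size = 2L,
                         max_epochs = 30L, patience = 10L, min_delta = 1e-4,
                         rounds = 3L, refine_epochs = 4L, seed = 1L) {
  if (rounds < 1) stop("train_config: rounds must be >= 1")
  structure(list(lr = lr, lr_refine = lr_refine,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 rounds = as.integer(rounds),
                 refine_epochs = as.integer(refine_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

## Core optimizer loop. inputs/targets: lists; val_* held-out lists.
## loss: "bce" (targets are arrays) or "ssim" (targets are image matrices).
## metric_fn(net) -> scalar to maximize on the validation fold.
fit_net <- function(net, inputs, targets, loss = c("bce", "ssim"),
                    lr, max_epochs, batch_size = 2L, patience = 10L,
                    min_delta = 1e-4, seed = 1L, frozen = character(0),
                    val_inputs = NULL, val_targets = NULL,
                    metric = c("none", "f1", "ssim"),
                    ssim_settings_ = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  metric <- match.arg(metric)
  if (is.null(ssim_settings_)) ssim_settings_ <- ssim_settings()
  opt <- adam_init()
  n <- length(inputs)
  best <- list(metric = -Inf, layers = net$layers, epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_metric = numeric(0))
  for (ep in seq_len(max_epochs)) {
    ord <- with_seed(derive_seed(seed, "epoch", ep), sample.int(n))
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, n)]
      xs <- lapply(inputs[idx], with_channel)
      fw <- nn_forward(net, xs, training = TRUE, frozen = frozen)
      net$layers <- fw$layers   # running BN stats
      dys <- vector("list", length(idx))
      bl <- 0
      for (i in seq_along(idx)) {
        z <- fw$out[[i]]
        if (loss == "bce") {
          tg <- with_channel(targets[[idx[i]]])
          l <- bce_logits_loss(z, tg)
        } else {
          l <- ssim_logits_loss(z, targets[[idx[i]]], ssim_settings_)
        }
        dys[[i]] <- array(l$grad / length(idx), dim(z))
        bl <- bl + l$loss / length(idx)
      }
      grads <- nn_backward(net, fw$caches, dys, frozen = frozen)
      net <- adam_step(net, grads, opt, lr)
      ep_loss <- ep_loss + bl; nb <- nb + 1
    }
    ep_loss <- ep_loss / nb
    vm <- NA_real_
    if (metric != "none" && length(val_inputs) > 0) {
      vm <- eval_metric(net, val_inputs, val_targets, metric, ssim_settings_)
      if (vm > best$metric + min_delta) {
        best <- list(metric = vm, layers = net$layers, epoch = ep)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_metric = vm))
    if (verbose) message(sprintf("epoch %d loss %.5f val %.4f", ep, ep_loss, vm))
    if (!is.finite(ep_loss)) stop("fit_net: training diverged (non-finite loss)")
    if (metric != "none" && wait >= patience) break
  }
  if (metric != "none" && is.finite(best$metric)) net$layers <- best$layers
  list(net = net, history = hist,
       best_metric = if (metric == "none") NA_real_ else best$metric)
}

eval_metric <- function(net, inputs, targets, metric, settings) {
  vals <- vapply(seq_along(inputs), function(i) {
    out <- nn_forward(net, list(with_channel(inputs[[i]])), training = FALSE)$out[[1]]
    p <- sigmoid(out)
    if (metric == "f1") {
      f1_score(p, with_channel(targets[[i]]))
    } else {
      d <- dim(p)
      ssim(gray_image(clip01(matrix(p, d[2], d[3]))),
           gray_image(clip01(as.matrix(targets[[i]]))), settings)
    }
  }, 0.0)
  mean(vals)
}
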