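# Minimal reverse-mode automatic differentiation over 2D feature maps.
#
# Feature maps are stored as dense matrices with one row per pixel and one
# column per channel. Row order is column-major within a sample (y fastest,
# then x), samples stacked along rows: row = y + (x-1)*h + (s-1)*h*w.
# This layout makes `as.vector(array(h, w, n))` the canonical flattening and
# lets convolutions run as one BLAS matrix product per layer (im2col).
#
# A tape records nodes in creation order; `ad_backward()` walks it in
# reverse, each node scattering its gradient into its parents. Only the op
# set needed by the splitting encoder-decoder is implemented.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), backward = NULL,
                    n = 1L, h = 1L, w = 1L) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$n <- as.integer(n); nd$h <- as.integer(h); nd$w <- as.integer(w)
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, val, n = 1L, h = 1L, w = 1L) {
  ad_node(tape, val, n = n, h = h, w = w)
}

ad_param <- function(tape, val) {
  nd <- ad_node(tape, val)
  nd$is_param <- TRUE
  nd
}

.acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

ad_backward <- function(tape, loss) {
  loss$grad <- matrix(1, nrow(loss$val), ncol(loss$val))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

# ---- cached index machinery -------------------------------------------------

.idx_cache <- new.env(parent = emptyenv())

.cached_idx <- function(key, build) {
  if (!exists(key, envir = .idx_cache, inherits = FALSE))
    assign(key, build(), envir = .idx_cache)
  get(key, envir = .idx_cache, inherits = FALSE)
}

.batch_rep <- function(base, n, hw_src) {
  # replicate a per-sample row index (0 = out of frame) across n samples
  if (n == 1L) return(as.integer(base))
  reps <- rep(base, times = n)
  shift <- rep((seq_len(n) - 1L) * hw_src, each = length(base))
  out <- reps + shift
  out[reps == 0L] <- 0L
  as.integer(out)
}

# concatenated 0-based row indices (-1 = zero padding), offset-major, for
# the compiled im2col gather
.conv_offsets <- function(n, h, w, kh, kw) {
  key <- paste("conv", n, h, w, kh, kw, sep = "_")
  .cached_idx(key, function() {
    ys <- rep(seq_len(h), times = w)
    xs <- rep(seq_len(w), each = h)
    dys <- seq_len(kh) - (kh + 1L) %/% 2L
    dxs <- seq_len(kw) - (kw + 1L) %/% 2L
    out <- integer(0)
    K <- 0L
    for (dx in dxs) for (dy in dys) {
      sy <- ys + dy; sx <- xs + dx
      ok <- sy >= 1L & sy <= h & sx >= 1L & sx <= w
      base <- ifelse(ok, sy + (sx - 1L) * h, 0L)
      out <- c(out, .batch_rep(base, n, h * w) - 1L)  # -1 marks padding
      K <- K + 1L
    }
    list(idx = out, K = K)
  })
}


.pool_offsets <- function(n, h, w) {
  # four injective index sets mapping the (h/2, w/2) grid into (h, w)
  key <- paste("pool", n, h, w, sep = "_")
  .cached_idx(key, function() {
    h2 <- h %/% 2L; w2 <- w %/% 2L
    ys <- rep(seq_len(h2), times = w2)
    xs <- rep(seq_len(w2), each = h2)
    out <- list()
    for (b in 0:1) for (a in 0:1) {
      sy <- 2L * (ys - 1L) + 1L + a
      sx <- 2L * (xs - 1L) + 1L + b
      base <- sy + (sx - 1L) * h
      out[[length(out) + 1L]] <- .batch_rep(base, n, h * w)
    }
    out
  })
}

.center_inner_rows <- function(n, H, W, h, w) {
  # rows of the centered (h, w) window inside an (H, W) frame;
  # odd margins drop/skip the extra pixel on the trailing side
  key <- paste("center", n, H, W, h, w, sep = "_")
  .cached_idx(key, function() {
    oy <- (H - h) %/% 2L
    ox <- (W - w) %/% 2L
    ys <- rep(seq_len(h) + oy, times = w)
    xs <- rep(seq_len(w) + ox, each = h)
    base <- ys + (xs - 1L) * H
    .batch_rep(base, n, H * W)
  })
}

.zgroup_rows <- function(nvol, nz, h, w) {
  # index sets: for each z, the rows of that slice across all volumes,
  # ordered to align with the (nvol * h * w)-row averaged output
  key <- paste("zg", nvol, nz, h, w, sep = "_")
  .cached_idx(key, function() {
    hw <- h * w
    lapply(seq_len(nz), function(z) {
      base <- rep(seq_len(hw), times = nvol)
      vol <- rep(seq_len(nvol) - 1L, each = hw)
      as.integer(base + (vol * nz + (z - 1L)) * hw)
    })
  })
}

# ---- ops --------------------------------------------------------------------

ad_conv2d <- function(tape, x, wt, bs, kh = 3L, kw = 3L) {
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  cin <- ncol(x$val)
  cout <- ncol(wt$val)
  stopifnot(nrow(wt$val) == kh * kw * cin)
  if (kh == 1L && kw == 1L) {
    out <- x$val %*% wt$val
    out <- sweep(out, 2L, as.vector(bs$val), "+")
    nd <- ad_node(tape, out, list(x, wt, bs), n = x$n, h = x$h, w = x$w,
                  backward = function(nd) {
                    g <- nd$grad
                    .acc_grad(x, g %*% t(wt$val))
                    .acc_grad(wt, crossprod(x$val, g))
                    .acc_grad(bs, matrix(colSums(g), 1L))
                  })
    return(nd)
  }
  off <- .conv_offsets(x$n, x$h, x$w, kh, kw)
  out <- .cpp_conv_fwd(x$val, wt$val, as.vector(bs$val), off$idx, off$K)
  nd <- ad_node(tape, out, list(x, wt, bs), n = x$n, h = x$h, w = x$w,
                backward = function(nd) {
                  bw <- .cpp_conv_bwd(x$val, wt$val, nd$grad, off$idx, off$K)
                  .acc_grad(x, bw$dX)
                  .acc_grad(wt, bw$dW)
                  .acc_grad(bs, matrix(bw$db, 1L))
                })
  nd
}

ad_avgpool2 <- function(tape, x) {
  stopifnot(x$h %% 2L == 0L, x$w %% 2L == 0L)
  idx <- .pool_offsets(x$n, x$h, x$w)
  out <- (x$val[idx[[1]], , drop = FALSE] + x$val[idx[[2]], , drop = FALSE] +
          x$val[idx[[3]], , drop = FALSE] + x$val[idx[[4]], , drop = FALSE]) / 4
  ad_node(tape, out, list(x), n = x$n, h = x$h %/% 2L, w = x$w %/% 2L,
          backward = function(nd) {
            g <- nd$grad / 4
            dX <- matrix(0, nrow(x$val), ncol(x$val))
            for (k in 1:4) dX[idx[[k]], ] <- dX[idx[[k]], , drop = FALSE] + g
            .acc_grad(x, dX)
          })
}

# fixed separable [1,2,1]/4 x [1,2,1]/4 smoothing (zero-padded); applying
# it after nearest-neighbor 2x upsampling realizes bilinear upsampling.
# The kernel is symmetric, so the op is self-adjoint: backward = forward.
ad_blur121 <- function(tape, x) {
  off <- .conv_offsets(x$n, x$h, x$w, 3L, 3L)
  wk <- as.numeric(outer(c(1, 2, 1) / 4, c(1, 2, 1) / 4))
  out <- .cpp_stencil(x$val, off$idx, wk)
  ad_node(tape, out, list(x), n = x$n, h = x$h, w = x$w,
          backward = function(nd)
            .acc_grad(x, .cpp_stencil(nd$grad, off$idx, wk)))
}

ad_upsample2 <- function(tape, x) {
  H <- 2L * x$h; W <- 2L * x$w
  idx <- .pool_offsets(x$n, H, W)   # out rows per input pixel
  out <- matrix(0, x$n * H * W, ncol(x$val))
  for (k in 1:4) out[idx[[k]], ] <- x$val
  ad_node(tape, out, list(x), n = x$n, h = H, w = W,
          backward = function(nd) {
            g <- nd$grad
            dX <- g[idx[[1]], , drop = FALSE] + g[idx[[2]], , drop = FALSE] +
                  g[idx[[3]], , drop = FALSE] + g[idx[[4]], , drop = FALSE]
            .acc_grad(x, dX)
          })
}

ad_pad_center <- function(tape, x, H, W) {
  stopifnot(H >= x$h, W >= x$w)
  if (H == x$h && W == x$w) return(x)
  rows <- .center_inner_rows(x$n, H, W, x$h, x$w)
  out <- matrix(0, x$n * H * W, ncol(x$val))
  out[rows, ] <- x$val
  ad_node(tape, out, list(x), n = x$n, h = H, w = W,
          backward = function(nd) .acc_grad(x, nd$grad[rows, , drop = FALSE]))
}

ad_crop_center <- function(tape, x, h, w) {
  stopifnot(h <= x$h, w <= x$w)
  if (h == x$h && w == x$w) return(x)
  rows <- .center_inner_rows(x$n, x$h, x$w, h, w)
  out <- x$val[rows, , drop = FALSE]
  ad_node(tape, out, list(x), n = x$n, h = h, w = w,
          backward = function(nd) {
            dX <- matrix(0, nrow(x$val), ncol(x$val))
            dX[rows, ] <- nd$grad
            .acc_grad(x, dX)
          })
}

ad_concat <- function(tape, x, y) {
  stopifnot(x$n == y$n, x$h == y$h, x$w == y$w)
  cx <- ncol(x$val)
  out <- cbind(x$val, y$val)
  ad_node(tape, out, list(x, y), n = x$n, h = x$h, w = x$w,
          backward = function(nd) {
            .acc_grad(x, nd$grad[, seq_len(cx), drop = FALSE])
            .acc_grad(y, nd$grad[, -seq_len(cx), drop = FALSE])
          })
}

ad_slice_cols <- function(tape, x, j1, j2) {
  out <- x$val[, j1:j2, drop = FALSE]
  ad_node(tape, out, list(x), n = x$n, h = x$h, w = x$w,
          backward = function(nd) {
            dX <- matrix(0, nrow(x$val), ncol(x$val))
            dX[, j1:j2] <- nd$grad
            .acc_grad(x, dX)
          })
}

ad_relu <- function(tape, x) {
  mask <- x$val > 0
  ad_node(tape, x$val * mask, list(x), n = x$n, h = x$h, w = x$w,
          backward = function(nd) .acc_grad(x, nd$grad * mask))
}

ad_add <- function(tape, x, y) {
  ad_node(tape, x$val + y$val, list(x, y), n = x$n, h = x$h, w = x$w,
          backward = function(nd) {
            .acc_grad(x, nd$grad)
            .acc_grad(y, nd$grad)
          })
}

ad_scale <- function(tape, x, s) {
  ad_node(tape, x$val * s, list(x), n = x$n, h = x$h, w = x$w,
          backward = function(nd) .acc_grad(x, nd$grad * s))
}

# channel-wise affine with constant coefficients (de-normalization)
ad_affine_cols <- function(tape, x, a, b) {
  out <- sweep(sweep(x$val, 2L, a, "*"), 2L, b, "+")
  ad_node(tape, out, list(x), n = x$n, h = x$h, w = x$w,
          backward = function(nd) .acc_grad(x, sweep(nd$grad, 2L, a, "*")))
}

ad_clamp <- function(tape, x, lo, hi) {
  mask <- x$val > lo & x$val < hi
  ad_node(tape, pmin(pmax(x$val, lo), hi), list(x), n = x$n, h = x$h, w = x$w,
          backward = function(nd) .acc_grad(x, nd$grad * mask))
}

# reparameterized draw z = mu + exp(lv / 2) * eps, eps a constant matrix
ad_sample_gauss <- function(tape, mu, lv, eps) {
  sd <- exp(0.5 * lv$val)
  ad_node(tape, mu$val + sd * eps, list(mu, lv), n = mu$n, h = mu$h, w = mu$w,
          backward = function(nd) {
            .acc_grad(mu, nd$grad)
            .acc_grad(lv, nd$grad * 0.5 * sd * eps)
          })
}

# pixel-wise KL( N(mu_q, e^lq) || N(mu_p, e^lp) ) for diagonal Gaussians
ad_kl_diag <- function(tape, mu_q, lv_q, mu_p, lv_p) {
  vq <- exp(lv_q$val); vp <- exp(lv_p$val)
  dm <- mu_q$val - mu_p$val
  val <- 0.5 * (lv_p$val - lv_q$val + (vq + dm * dm) / vp - 1)
  ad_node(tape, val, list(mu_q, lv_q, mu_p, lv_p),
          n = mu_q$n, h = mu_q$h, w = mu_q$w,
          backward = function(nd) {
            g <- nd$grad
            .acc_grad(mu_q, g * dm / vp)
            .acc_grad(mu_p, -g * dm / vp)
            .acc_grad(lv_q, g * 0.5 * (vq / vp - 1))
            .acc_grad(lv_p, g * 0.5 * (1 - (vq + dm * dm) / vp))
          })
}

# mean over the z-groups of a slice-batched tensor (n = nvol * nz)
ad_zmean <- function(tape, x, nz) {
  stopifnot(x$n %% nz == 0L)
  nvol <- x$n %/% nz
  idx <- .zgroup_rows(nvol, nz, x$h, x$w)
  out <- matrix(0, nvol * x$h * x$w, ncol(x$val))
  for (z in seq_len(nz)) out <- out + x$val[idx[[z]], , drop = FALSE]
  out <- out / nz
  ad_node(tape, out, list(x), n = nvol, h = x$h, w = x$w,
          backward = function(nd) {
            g <- nd$grad / nz
            dX <- matrix(0, nrow(x$val), ncol(x$val))
            for (z in seq_len(nz)) dX[idx[[z]], ] <- g
            .acc_grad(x, dX)
          })
}

ad_sum <- function(tape, x) {
  ad_node(tape, matrix(sum(x$val), 1L, 1L), list(x),
          backward = function(nd) {
            .acc_grad(x, matrix(nd$grad[1L], nrow(x$val), ncol(x$val)))
          })
}

# per-pixel Gaussian negative log-likelihood with learned log-variance
ad_gauss_nll <- function(tape, mu, lv, target) {
  r <- target - mu$val
  ilv <- exp(-lv$val)
  val <- 0.5 * (log(2 * pi) + lv$val + r * r * ilv)
  ad_node(tape, val, list(mu, lv), n = mu$n, h = mu$h, w = mu$w,
          backward = function(nd) {
            g <- nd$grad
            .acc_grad(mu, -g * r * ilv)
            .acc_grad(lv, g * 0.5 * (1 - r * r * ilv))
          })
}

# per-pixel negative log-likelihood of a noisy target under a noise model,
# differentiable in the predicted clean signal
ad_noise_nll <- function(tape, pred, target, model) {
  ll <- noise_loglik_grad(model, target, pred$val)
  ad_node(tape, -ll$loglik, list(pred), n = pred$n, h = pred$h, w = pred$w,
          backward = function(nd) .acc_grad(pred, -nd$grad * ll$dsignal))
}
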