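#' Lateral-contextualization patches
#'
#' The network input for one prediction is a *primary* patch plus `L`
#' context patches: context level `l` covers a window `2^l` times larger,
#' centered on the primary patch, and is downscaled by block averaging back
#' to the primary patch's pixel dimensions. The network therefore sees the
#' surroundings at progressively lower resolution without growing its
#' spatial extent. With the deep-context default of
#' `multiscale_lowres_count = 3`, two context levels accompany the primary
#' input (`L = 2`).
#'
#' @name lc_patching
NULL

# crop with out-of-frame handling
padded_crop <- function(img, y1, y2, x1, x2, pad_mode = c("reflect", "zero")) {
  pad_mode <- match.arg(pad_mode)
  h <- nrow(img); w <- ncol(img)
  ys <- y1:y2; xs <- x1:x2
  if (pad_mode == "reflect") {
    ry <- .reflect_any(ys, h)
    rx <- .reflect_any(xs, w)
    img[ry, rx, drop = FALSE]
  } else {
    out <- matrix(0, length(ys), length(xs))
    iy <- ys >= 1L & ys <= h
    ix <- xs >= 1L & xs <= w
    out[iy, ix] <- img[ys[iy], xs[ix], drop = FALSE]
    out
  }
}

# symmetric reflection of arbitrary integer indices into 1..n
.reflect_any <- function(idx, n) {
  period <- 2L * n
  m <- ((idx - 1L) %% period) + 1L
  m[m > n] <- period - m[m > n] + 1L
  m
}

#' Extract a primary patch and its context pyramid
#'
#' @param frame source image (matrix `H x W`)
#' @param center patch center `c(y, x)`; the primary window spans
#'   `center - size/2 + 1 .. center + size/2`
#' @param size primary patch side length (even)
#' @param L number of context levels (>= 0)
#' @param pad_mode boundary handling for context windows that exceed the
#'   frame: `"reflect"` (default) or `"zero"`; the primary window itself
#'   must lie inside the frame
#' @return an `lc_patch`: list with `primary` (`size x size` matrix),
#'   `contexts` (list of `L` matrices of identical dimensions), `center`,
#'   `L`
#' @export
extract_lc_patch <- function(frame, center, size, L = 0L,
                             pad_mode = c("reflect", "zero")) {
  pad_mode <- match.arg(pad_mode)
  stopifnot(size %% 2L == 0L, L >= 0L)
  cy <- center[1L]; cx <- center[2L]
  y1 <- cy - size %/% 2L + 1L; y2 <- cy + size %/% 2L
  x1 <- cx - size %/% 2L + 1L; x2 <- cx + size %/% 2L
  if (y1 < 1L || x1 < 1L || y2 > nrow(frame) || x2 > ncol(frame))
    stop("extract_lc_patch: primary window outside frame")
  primary <- frame[y1:y2, x1:x2, drop = FALSE]
  contexts <- vector("list", L)
  if (L > 0L) for (l in seq_len(L)) {
    f <- 2L^l
    half <- (size * f) %/% 2L
    win <- padded_crop(frame, cy - half + 1L, cy + half,
                       cx - half + 1L, cx + half, pad_mode)
    contexts[[l]] <- block_downscale(win, f)
  }
  structure(list(primary = primary, contexts = contexts,
                 center = c(cy, cx), L = L),
            class = "lc_patch")
}

#' Build a seeded training-patch sampler for a mixing task
#'
#' Returns a closure `sampler(n, seed)` producing batches of aligned
#' `(input pyramid, noisy targets, clean targets)` according to the task's
#' training mode:
#' * mode I: targets are co-located crops of the noisy channels, the input
#'   is their weighted sum (full-frame, so context levels are consistent).
#' * mode II: each channel crop comes from an independent location; input
#'   and context levels are the sums of the per-channel pyramids.
#' * mode IIb: crops are drawn from pure-region lists; `L` must be 0.
#' * mode III: the input comes from a separately simulated superimposed
#'   frame carrying its own noise realization.
#' * scaled-copy tasks (`similarity_scale` set) behave like mode II with
#'   both channels drawn from the same source, the second scaled.
#'
#' Noise is applied once per frame (not per patch), like a real
#' acquisition. Patch centers are sampled uniformly over the valid region.
#'
#' @param stack a clean `channel_stack` (modes I/III), a list of
#'   single-channel stacks (mode II), a single-channel stack or matrix
#'   (scaled-copy), or `list(a = , b = )` of pure-region crop lists (IIb)
#' @param task a [mix_task()]
#' @param size primary patch side length (even)
#' @param L context levels; forced to 0 for mode IIb (small crops cannot
#'   support context pyramids)
#' @param frame_seed seed for the per-frame noise realizations
#' @return function `(n, seed)` returning a batch: list with `primary`
#'   `(h, w, n)`, `contexts` (list of `L` arrays `(h, w, n)`), `targets`
#'   and `clean` `(h, w, k, n)`, `centers` `(n, 2)`
#' @export
make_patch_sampler <- function(stack, task, size, L = 0L, frame_seed = 99L) {
  stopifnot(inherits(task, "mix_task"), size %% 2L == 0L)
  if (task$mode == "IIb") {
    if (L > 0L)
      stop("make_patch_sampler: lateral context must be disabled (L = 0) ",
           "for mode IIb")
    return(.sampler_iib(stack, task, size))
  }
  if (!is.null(task$similarity_scale))
    return(.sampler_scaled_copy(stack, task, size, L, frame_seed))
  switch(task$mode,
         I = .sampler_frame_modes(stack, task, size, L, frame_seed, mode3 = FALSE),
         III = .sampler_frame_modes(stack, task, size, L, frame_seed, mode3 = TRUE),
         II = .sampler_mode_ii(stack, task, size, L, frame_seed))
}

.noise_with <- function(img, spec, seed) {
  apply_noise(img, noise_spec(spec$gaussian_sigma, spec$poisson_scale, seed))
}

.empty_batch <- function(h, w, k, L, n) {
  list(primary = array(0, c(h, w, n)),
       contexts = if (L > 0L) lapply(seq_len(L), function(l)
         array(0, c(h, w, n))) else list(),
       targets = array(0, c(h, w, k, n)),
       clean = array(0, c(h, w, k, n)),
       centers = matrix(0L, n, 2L))
}

.valid_center_range <- function(H, W, size) {
  half <- size %/% 2L
  list(y = c(half, H - half), x = c(half, W - half))
}

.sampler_frame_modes <- function(stack, task, size, L, frame_seed, mode3) {
  k <- task$k
  stopifnot(n_channels(stack) == k)
  H <- dim(stack$data)[2L]; W <- dim(stack$data)[3L]
  clean_ch <- lapply(seq_len(k), function(i) stack_channel(stack, i))
  noisy_ch <- lapply(seq_len(k), function(i)
    .noise_with(clean_ch[[i]], task$noise, derive_seed(frame_seed,
                                                       paste0("ch", i))))
  mixed_clean <- Reduce(`+`, Map(function(w, m) w * m,
                                 as.list(task$weights), clean_ch))
  input_frame <- if (mode3) {
    .noise_with(mixed_clean, task$noise, derive_seed(frame_seed, "mix"))
  } else {
    Reduce(`+`, Map(function(w, m) w * m, as.list(task$weights), noisy_ch))
  }
  rng <- .valid_center_range(H, W, size)
  function(n, seed) {
    stopifnot(n >= 1L)
    if (size > H || size > W) stop("patch larger than frame")
    with_seed(seed, {
      b <- .empty_batch(size, size, k, L, n)
      for (j in seq_len(n)) {
        cy <- sample(rng$y[1L]:rng$y[2L], 1L)
        cx <- sample(rng$x[1L]:rng$x[2L], 1L)
        lp <- extract_lc_patch(input_frame, c(cy, cx), size, L)
        b$primary[, , j] <- lp$primary
        if (L > 0L) for (l in seq_len(L))
          b$contexts[[l]][, , j] <- lp$contexts[[l]]
        y1 <- cy - size %/% 2L + 1L; x1 <- cx - size %/% 2L + 1L
        for (i in seq_len(k)) {
          b$targets[, , i, j] <- crop_at(noisy_ch[[i]], y1, x1, size, size)
          b$clean[, , i, j] <- crop_at(clean_ch[[i]], y1, x1, size, size)
        }
        b$centers[j, ] <- c(cy, cx)
      }
      b
    })
  }
}

.sampler_mode_ii <- function(stacks, task, size, L, frame_seed) {
  k <- task$k
  if (length(stacks) < k)
    stop("make_patch_sampler: mode II needs >= k source stacks")
  clean <- lapply(stacks[seq_len(k)], function(s) stack_channel(s, 1L))
  noisy <- lapply(seq_len(k), function(i)
    .noise_with(clean[[i]], task$noise, derive_seed(frame_seed,
                                                    paste0("ii", i))))
  function(n, seed) {
    stopifnot(n >= 1L)
    with_seed(seed, {
      b <- .empty_batch(size, size, k, L, n)
      for (j in seq_len(n)) {
        for (i in seq_len(k)) {
          H <- nrow(clean[[i]]); W <- ncol(clean[[i]])
          if (size > H || size > W) stop("patch larger than frame")
          rng <- .valid_center_range(H, W, size)
          cy <- sample(rng$y[1L]:rng$y[2L], 1L)
          cx <- sample(rng$x[1L]:rng$x[2L], 1L)
          lp <- extract_lc_patch(noisy[[i]], c(cy, cx), size, L)
          wgt <- task$weights[i]
          b$primary[, , j] <- b$primary[, , j] + wgt * lp$primary
          if (L > 0L) for (l in seq_len(L))
            b$contexts[[l]][, , j] <- b$contexts[[l]][, , j] +
              wgt * lp$contexts[[l]]
          y1 <- cy - size %/% 2L + 1L; x1 <- cx - size %/% 2L + 1L
          b$targets[, , i, j] <- crop_at(noisy[[i]], y1, x1, size, size)
          b$clean[, , i, j] <- crop_at(clean[[i]], y1, x1, size, size)
          if (i == 1L) b$centers[j, ] <- c(cy, cx)
        }
      }
      b
    })
  }
}

.sampler_scaled_copy <- function(stack, task, size, L, frame_seed) {
  s <- task$similarity_scale
  img <- if (inherits(stack, "channel_stack")) stack_channel(stack, 1L)
         else stack
  clean <- img
  noisy <- .noise_with(clean, task$noise, derive_seed(frame_seed, "sc"))
  scales <- c(1, s)
  function(n, seed) {
    stopifnot(n >= 1L)
    with_seed(seed, {
      b <- .empty_batch(size, size, 2L, L, n)
      H <- nrow(clean); W <- ncol(clean)
      rng <- .valid_center_range(H, W, size)
      for (j in seq_len(n)) {
        for (i in 1:2) {
          cy <- sample(rng$y[1L]:rng$y[2L], 1L)
          cx <- sample(rng$x[1L]:rng$x[2L], 1L)
          lp <- extract_lc_patch(noisy, c(cy, cx), size, L)
          wgt <- task$weights[i] * scales[i]
          b$primary[, , j] <- b$primary[, , j] + wgt * lp$primary
          if (L > 0L) for (l in seq_len(L))
            b$contexts[[l]][, , j] <- b$contexts[[l]][, , j] +
              wgt * lp$contexts[[l]]
          y1 <- cy - size %/% 2L + 1L; x1 <- cx - size %/% 2L + 1L
          b$targets[, , i, j] <- scales[i] * crop_at(noisy, y1, x1, size, size)
          b$clean[, , i, j] <- scales[i] * crop_at(clean, y1, x1, size, size)
          if (i == 1L) b$centers[j, ] <- c(cy, cx)
        }
      }
      b
    })
  }
}

.sampler_iib <- function(regions, task, size) {
  if (is.null(regions$a) || is.null(regions$b))
    stop("make_patch_sampler: mode IIb expects list(a = crops, b = crops)")
  if (length(regions$a) == 0L || length(regions$b) == 0L)
    stop("make_patch_sampler: empty crop list")
  noise <- task$noise
  function(n, seed) {
    stopifnot(n >= 1L)
    with_seed(seed, {
      b <- .empty_batch(size, size, 2L, 0L, n)
      for (j in seq_len(n)) {
        pr <- assemble_mode_IIb(regions$a, regions$b, size,
                                seed = sample.int(2^30, 1L))
        noisy_t <- array(0, c(2L, size, size))
        for (i in 1:2)
          noisy_t[i, , ] <- .noise_with(pmax(pr$targets[i, , ], 0), noise,
                                        sample.int(2^30, 1L))
        b$primary[, , j] <- noisy_t[1L, , ] + noisy_t[2L, , ]
        for (i in 1:2) {
          b$targets[, , i, j] <- noisy_t[i, , ]
          b$clean[, , i, j] <- pr$targets[i, , ]
        }
      }
      b
    })
  }
}
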