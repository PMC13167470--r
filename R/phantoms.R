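#' Multi-channel image container
#'
#' Holds `k` co-registered intensity channels on a photon-count-like scale,
#' stored as an array of shape `(k, H, W)` for 2D data or `(k, Z, H, W)` for
#' volumetric data. Clean phantom channels are non-negative; noisy channels
#' may dip below zero because of read noise.
#'
#' @param data numeric array `(k, H, W)` or `(k, Z, H, W)`
#' @param channel_names optional character vector of length `k`
#' @param voxel_size optional physical size per axis in nm
#' @param is_noisy logical flag per channel
#' @return an object of class `channel_stack`
#' @export
channel_stack <- function(data, channel_names = NULL, voxel_size = NULL,
                          is_noisy = FALSE) {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L))
  k <- dim(data)[1L]
  stopifnot(k >= 1L)
  if (!all(is.finite(data))) stop("channel_stack: non-finite intensities")
  if (is.null(channel_names)) channel_names <- paste0("C", seq_len(k))
  stopifnot(length(channel_names) == k)
  is_noisy <- rep_len(is_noisy, k)
  structure(list(data = data, channel_names = channel_names,
                 voxel_size = voxel_size, is_noisy = is_noisy),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("<channel_stack> k =", d[1L], " spatial:",
      paste(d[-1L], collapse = " x "),
      if (any(x$is_noisy)) " (noisy)" else " (clean)", "\n")
  invisible(x)
}

#' @rdname channel_stack
#' @param stack a `channel_stack`
#' @export
n_channels <- function(stack) dim(stack$data)[1L]

is_3d_stack <- function(stack) length(dim(stack$data)) == 4L

#' Extract channel `i` as a matrix `(H, W)` (or array `(Z, H, W)`)
#' @param stack a `channel_stack`
#' @param i channel index
#' @export
stack_channel <- function(stack, i) {
  d <- dim(stack$data)
  if (length(d) == 3L) array(stack$data[i, , ], d[-1L])
  else array(stack$data[i, , , ], d[-1L])
}

#' Noise specification for the synthetic generator
#'
#' Noise is applied as `Poisson(x / poisson_scale) * poisson_scale +
#' N(0, gaussian_sigma)` when `poisson_scale > 0` (so the shot-noise
#' variance at signal level `v` is `v * poisson_scale`), and as plain
#' additive Gaussian noise otherwise.
#'
#' @param gaussian_sigma additive read-noise s.d. in intensity units (>= 0)
#' @param poisson_scale photon-conversion factor (>= 0; 0 disables shot
#'   noise)
#' @param seed RNG seed used by [apply_noise()]
#' @export
noise_spec <- function(gaussian_sigma = 0, poisson_scale = 0, seed = 1L) {
  if (gaussian_sigma < 0) stop("noise_spec: gaussian_sigma must be >= 0")
  if (poisson_scale < 0) stop("noise_spec: poisson_scale must be >= 0")
  structure(list(gaussian_sigma = gaussian_sigma,
                 poisson_scale = poisson_scale, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Apply Poisson-Gaussian noise to a clean image
#'
#' @param image numeric array, non-negative wherever `poisson_scale > 0`
#' @param spec a [noise_spec()]
#' @return noisy array of the same shape
#' @export
apply_noise <- function(image, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  with_seed(spec$seed, {
    out <- image
    if (spec$poisson_scale > 0) {
      if (any(image < 0))
        stop("apply_noise: negative intensities with poisson_scale > 0")
      out <- stats::rpois(length(image), as.numeric(image) /
                            spec$poisson_scale) * spec$poisson_scale
    }
    if (spec$gaussian_sigma > 0)
      out <- out + stats::rnorm(length(image), 0, spec$gaussian_sigma)
    array(as.numeric(out), dim(image) %||% length(image))
  })
}

#' Task description for building training pairs
#'
#' Bundles the channel count, per-channel mixing weights (the "skew", e.g.
#' `c(2, 1)` for a 66:33 brightness ratio), the training mode, the noise
#' specification, and the optional scale factor of the scaled-copy
#' similarity task.
#'
#' @param k channel count, 2..4
#' @param weights `k` positive mixing weights (default equal)
#' @param mode one of `"I"`, `"II"`, `"IIb"`, `"III"`
#' @param noise a [noise_spec()]
#' @param similarity_scale optional scalar >= 1; only valid for `k = 2`
#'   scaled-copy tasks where both channels derive from the same source
#' @export
mix_task <- function(k, weights = rep(1, k), mode = c("I", "II", "IIb", "III"),
                     noise = noise_spec(), similarity_scale = NULL) {
  mode <- match.arg(mode)
  stopifnot(k %in% 2:4, length(weights) == k, all(weights > 0))
  if (!is.null(similarity_scale)) {
    if (k != 2L) stop("mix_task: similarity_scale requires k = 2")
    if (similarity_scale < 1) stop("mix_task: similarity_scale must be >= 1")
  }
  structure(list(k = as.integer(k), weights = as.numeric(weights),
                 mode = mode, noise = noise,
                 similarity_scale = similarity_scale),
            class = "mix_task")
}

# ---- structure rendering ----------------------------------------------------

.add_patch_fn <- function(canvas, cy, cx, r, fn) {
  h <- nrow(canvas); w <- ncol(canvas)
  y1 <- max(1L, floor(cy - r)); y2 <- min(h, ceiling(cy + r))
  x1 <- max(1L, floor(cx - r)); x2 <- min(w, ceiling(cx + r))
  if (y1 > y2 || x1 > x2) return(canvas)
  ys <- y1:y2; xs <- x1:x2
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  canvas[ys, xs] <- canvas[ys, xs] + fn(dy, dx)
  canvas
}

.render_2d <- function(kind, h, w, density, amp_range, size_scale = 1,
                       wiggle = 0.15) {
  n_obj <- stats::rpois(1L, density * h * w)
  canvas <- matrix(0, h, w)
  if (n_obj == 0L) return(canvas)
  for (i in seq_len(n_obj)) {
    amp <- stats::runif(1L, amp_range[1L], amp_range[2L])
    cy <- stats::runif(1L, 1, h); cx <- stats::runif(1L, 1, w)
    if (kind == "puncta") {
      s <- size_scale * stats::runif(1L, 1, 2)
      canvas <- .add_patch_fn(canvas, cy, cx, 3 * s, function(dy, dx)
        amp * exp(-(dy^2 + dx^2) / (2 * s^2)))
    } else if (kind == "rings") {
      rad <- size_scale * stats::runif(1L, 5, 10)
      wd <- 0.9 * size_scale
      canvas <- .add_patch_fn(canvas, cy, cx, rad + 3 * wd, function(dy, dx) {
        d <- sqrt(dy^2 + dx^2)
        amp * exp(-(d - rad)^2 / (2 * wd^2))
      })
    } else if (kind == "blobs") {
      sy <- size_scale * stats::runif(1L, 4, 9)
      sx <- size_scale * stats::runif(1L, 4, 9)
      th <- stats::runif(1L, 0, pi)
      canvas <- .add_patch_fn(canvas, cy, cx, 3 * max(sy, sx),
                              function(dy, dx) {
        u <- cos(th) * dy + sin(th) * dx
        v <- -sin(th) * dy + cos(th) * dx
        amp * exp(-(u^2 / sy^2 + v^2 / sx^2) / 2)
      })
    } else if (kind == "filaments") {
      nst <- round(stats::runif(1L, 40, 120))
      th <- stats::runif(1L, 0, 2 * pi)
      py <- cy; px <- cx
      for (t in seq_len(nst)) {
        th <- th + stats::rnorm(1L, 0, wiggle)
        py <- py + sin(th); px <- px + cos(th)
        canvas <- .add_patch_fn(canvas, py, px, 2.2 * size_scale,
                                function(dy, dx)
          amp * exp(-(dy^2 + dx^2) / (2 * (0.8 * size_scale)^2)))
      }
    } else stop("generate_structure_channel: unknown kind '", kind, "'")
  }
  canvas
}

#' Generate a single-structure phantom channel
#'
#' Renders a clean (noise-free, zero-background) image of one of four
#' structural archetypes spanning the morphologies encountered in
#' fluorescence microscopy: `filaments` (random-walk polylines, e.g.
#' microtubules), `blobs` (soft anisotropic Gaussians, e.g. nuclei),
#' `puncta` (small Gaussian spots, e.g. kinetochores or vesicles) and
#' `rings` (annuli, e.g. nuclear envelope cross-sections). Object count is
#' Poisson with mean `density * prod(shape)`; per-object peak amplitude is
#' drawn uniformly from `amp_range`.
#'
#' For a 3-long `shape` the rendered 2D plane is replicated along z.
#'
#' @param kind one of `"filaments"`, `"blobs"`, `"puncta"`, `"rings"`
#' @param shape spatial dimensions `c(H, W)` or `c(Z, H, W)`, all >= 32
#' @param density expected objects per pixel (>= 0)
#' @param seed RNG seed; output is bit-reproducible for a fixed seed
#' @param amp_range peak-intensity range of rendered objects
#' @param size_scale multiplier on the characteristic object size
#' @param wiggle direction-noise s.d. of filament random walks (radians
#'   per step); small values give straight bar-like strokes
#' @return a `channel_stack` with `k = 1`
#' @export
generate_structure_channel <- function(kind, shape, density, seed = 1L,
                                       amp_range = c(80, 120),
                                       size_scale = 1, wiggle = 0.15) {
  kind <- as.character(kind)
  if (!kind %in% c("filaments", "blobs", "puncta", "rings"))
    stop("generate_structure_channel: unknown kind '", kind, "'")
  stopifnot(density >= 0, all(shape >= 32L),
            length(shape) %in% c(2L, 3L))
  with_seed(seed, {
    if (length(shape) == 2L) {
      img <- .render_2d(kind, shape[1L], shape[2L], density, amp_range,
                        size_scale, wiggle)
      channel_stack(array(img, c(1L, shape)), channel_names = kind)
    } else {
      img <- .render_2d(kind, shape[2L], shape[3L], density, amp_range,
                        size_scale, wiggle)
      vol <- aperm(array(img, c(shape[2L], shape[3L], shape[1L])),
                   c(3L, 1L, 2L))
      channel_stack(array(vol, c(1L, shape)), channel_names = kind)
    }
  })
}

#' Two channels with a controlled colocalization level
#'
#' Builds a pair of smooth random fields sharing a common component so that
#' their Pearson correlation is approximately `rho`; used to verify that
#' mode-I pair assembly preserves, and mode-II assembly destroys,
#' cross-channel spatial correlation.
#'
#' @param shape `c(H, W)`
#' @param rho target correlation in `[0, 1)`
#' @param seed RNG seed
#' @param sigma smoothing length of the random fields, pixels
#' @return a `channel_stack` with `k = 2`
#' @export
generate_colocalized_channels <- function(shape, rho = 0.6, seed = 1L,
                                          sigma = 4) {
  stopifnot(length(shape) == 2L, rho >= 0, rho < 1)
  with_seed(seed, {
    h <- shape[1L]; w <- shape[2L]
    smooth_field <- function() {
      f <- gauss_blur(matrix(stats::rnorm(h * w), h, w), sigma)
      (f - mean(f)) / stats::sd(f)
    }
    co <- smooth_field(); xa <- smooth_field(); xb <- smooth_field()
    a <- sqrt(rho) * co + sqrt(1 - rho) * xa
    b <- sqrt(rho) * co + sqrt(1 - rho) * xb
    # shift/scale to a non-negative intensity scale; a common offset keeps
    # the correlation intact, clipping is negligible at 4 s.d.
    a <- pmax(a * 25 + 100, 0)
    b <- pmax(b * 25 + 100, 0)
    dat <- array(0, c(2L, h, w))
    dat[1L, , ] <- a; dat[2L, , ] <- b
    channel_stack(dat, channel_names = c("A", "B"))
  })
}

#' Pixel-wise weighted summation of channels
#'
#' The superimposed single-channel image is the weighted pixel-wise sum of
#' the structure channels, mirroring what a broad-filter acquisition
#' records.
#'
#' @param stack a `channel_stack` (clean or noisy)
#' @param weights `k` positive weights; `c(2, 1)` realizes a 66:33 skew
#' @return a matrix `(H, W)` (or array `(Z, H, W)`)
#' @export
mix_channels <- function(stack, weights = rep(1, n_channels(stack))) {
  k <- n_channels(stack)
  if (length(weights) != k)
    stop("mix_channels: ", length(weights), " weights for ", k, " channels")
  stopifnot(all(weights > 0))
  out <- weights[1L] * stack_channel(stack, 1L)
  if (k > 1L) for (i in 2:k) out <- out + weights[i] * stack_channel(stack, i)
  out
}

# crop helper: matrix (H, W), top-left (y, x), size (h, w)
crop_at <- function(img, y, x, h, w) {
  if (y < 1L || x < 1L || y + h - 1L > nrow(img) || x + w - 1L > ncol(img))
    stop("crop_at: window outside frame")
  img[y:(y + h - 1L), x:(x + w - 1L), drop = FALSE]
}

#' Assemble a training pair in mode I (co-located multiplexed channels)
#'
#' All target channels come from the same spatial location of the same
#' multiplexed stack; the input is their weighted pixel-wise sum, so any
#' spatial correlation between the structures is preserved and
#' `input == sum(weights * targets)` holds exactly on clean data.
#'
#' @param stack multiplexed `channel_stack` with `k` channels
#' @param origin top-left corner `c(y, x)` of the patch
#' @param size patch side length (or `c(h, w)`)
#' @param weights mixing weights
#' @return list with `input` (matrix), `targets` (array `(k, h, w)`),
#'   `origin`
#' @export
assemble_mode_I <- function(stack, origin, size,
                            weights = rep(1, n_channels(stack))) {
  size <- rep_len(size, 2L)
  k <- n_channels(stack)
  tg <- array(0, c(k, size[1L], size[2L]))
  for (i in seq_len(k))
    tg[i, , ] <- crop_at(stack_channel(stack, i), origin[1L], origin[2L],
                         size[1L], size[2L])
  inp <- matrix(0, size[1L], size[2L])
  for (i in seq_len(k)) inp <- inp + weights[i] * tg[i, , ]
  list(input = inp, targets = tg, origin = origin)
}

#' Assemble a training pair in mode II (uncorrelated single-structure images)
#'
#' Each channel's crop is drawn from an independently chosen source image
#' and location, then the crops are summed. Cross-channel spatial
#' correlation is destroyed in expectation.
#'
#' @param stacks list of `k` (or more) single-channel `channel_stack`s, or a
#'   list of lists (several frames per structure type)
#' @param size patch side length
#' @param k number of channels to assemble
#' @param weights mixing weights
#' @param seed RNG seed controlling the pairing sequence
#' @param origins optional list of `k` fixed `c(y, x)` origins (forcing one
#'   location per channel reduces mode II to mode I on that pairing)
#' @return list with `input`, `targets`, `origins`
#' @export
assemble_mode_II <- function(stacks, size, k = length(stacks),
                             weights = rep(1, k), seed = 1L,
                             origins = NULL) {
  if (length(stacks) < k)
    stop("assemble_mode_II: need at least ", k, " source stacks")
  size <- rep_len(size, 2L)
  with_seed(seed, {
    tg <- array(0, c(k, size[1L], size[2L]))
    origs <- vector("list", k)
    for (i in seq_len(k)) {
      src <- stacks[[i]]
      img <- if (inherits(src, "channel_stack")) stack_channel(src, 1L)
             else stack_channel(src[[sample.int(length(src), 1L)]], 1L)
      if (is.null(origins)) {
        y <- sample.int(nrow(img) - size[1L] + 1L, 1L)
        x <- sample.int(ncol(img) - size[2L] + 1L, 1L)
      } else { y <- origins[[i]][1L]; x <- origins[[i]][2L] }
      origs[[i]] <- c(y, x)
      tg[i, , ] <- crop_at(img, y, x, size[1L], size[2L])
    }
    inp <- matrix(0, size[1L], size[2L])
    for (i in seq_len(k)) inp <- inp + weights[i] * tg[i, , ]
    list(input = inp, targets = tg, origins = origs)
  })
}

#' Assemble a training pair in mode IIb (manually cropped pure regions)
#'
#' For data where two structure classes mix in some areas but appear in
#' isolation elsewhere: training pairs are built by randomly pairing one
#' pure-structure crop of each class and summing them. Crops may be small
#' (down to 100 x 100 pixels in practice), which is why lateral
#' contextualization must be disabled for this mode.
#'
#' @param pure_regions_a,pure_regions_b non-empty lists of matrices, each
#'   containing only one structure class
#' @param size patch side length; crops smaller than `size` are
#'   reflect-padded, larger ones are cropped at a random location
#' @param seed RNG seed
#' @return list with `input`, `targets` (`(2, h, w)`), `pair` (chosen
#'   indices)
#' @export
assemble_mode_IIb <- function(pure_regions_a, pure_regions_b, size,
                              seed = 1L) {
  if (length(pure_regions_a) == 0L || length(pure_regions_b) == 0L)
    stop("assemble_mode_IIb: empty crop list")
  size <- rep_len(size, 2L)
  with_seed(seed, {
    pick <- function(lst) {
      i <- sample.int(length(lst), 1L)
      m <- reflect_pad_to(lst[[i]], size[1L], size[2L])
      y <- if (nrow(m) > size[1L])
        sample.int(nrow(m) - size[1L] + 1L, 1L) else 1L
      x <- if (ncol(m) > size[2L])
        sample.int(ncol(m) - size[2L] + 1L, 1L) else 1L
      list(i = i, m = crop_at(m, y, x, size[1L], size[2L]))
    }
    a <- pick(pure_regions_a); b <- pick(pure_regions_b)
    tg <- array(0, c(2L, size[1L], size[2L]))
    tg[1L, , ] <- a$m; tg[2L, , ] <- b$m
    list(input = a$m + b$m, targets = tg, pair = c(a$i, b$i))
  })
}

#' Assemble a training pair in mode III (acquired superimposed input)
#'
#' The input crop is taken from a separately acquired superimposed channel
#' at the same location as the targets, so its noise realization is
#' statistically independent of the target noise (it equals the sum of the
#' clean channels only in expectation).
#'
#' @param stack `channel_stack` with `k + 1` channels, the last being the
#'   acquired superimposed channel
#' @param origin top-left corner `c(y, x)`
#' @param size patch side length
#' @return list with `input`, `targets` (`(k, h, w)`), `origin`
#' @export
assemble_mode_III <- function(stack, origin, size) {
  k1 <- n_channels(stack)
  if (k1 < 3L)
    stop("assemble_mode_III: stack must hold k targets plus the acquired ",
         "superimposed channel")
  size <- rep_len(size, 2L)
  k <- k1 - 1L
  tg <- array(0, c(k, size[1L], size[2L]))
  for (i in seq_len(k))
    tg[i, , ] <- crop_at(stack_channel(stack, i), origin[1L], origin[2L],
                         size[1L], size[2L])
  inp <- crop_at(stack_channel(stack, k1), origin[1L], origin[2L],
                 size[1L], size[2L])
  list(input = inp, targets = tg, origin = origin)
}

#' Scaled-copy similarity task
#'
#' Builds the provably hard two-channel task in which both channels are
#' draws from the same structural distribution: channel 1 is a crop of the
#' source image, channel 2 an independently located crop multiplied by
#' `s >= 1`. At `s = 1` the two channels are statistically identical and
#' unmixing is impossible in principle; increasing `s` makes the channels
#' distinguishable by brightness. Factors of interest include 1.032, 1.063,
#' 1.125, 1.25, 1.5 and 2.
#'
#' @param frame single-channel source image (matrix or `channel_stack`)
#' @param s intensity scale factor, >= 1
#' @param size patch side length
#' @param seed RNG seed
#' @return a `channel_stack` with `k = 2` and attribute `similarity_scale`
#' @export
make_scaled_copy_task <- function(frame, s, size, seed = 1L) {
  if (s < 1) stop("make_scaled_copy_task: s must be >= 1 (swap channels ",
                  "to normalize)")
  img <- if (inherits(frame, "channel_stack")) stack_channel(frame, 1L)
         else frame
  size <- rep_len(size, 2L)
  with_seed(seed, {
    draw <- function() {
      y <- sample.int(nrow(img) - size[1L] + 1L, 1L)
      x <- sample.int(ncol(img) - size[2L] + 1L, 1L)
      crop_at(img, y, x, size[1L], size[2L])
    }
    dat <- array(0, c(2L, size[1L], size[2L]))
    dat[1L, , ] <- draw()
    dat[2L, , ] <- s * draw()
    out <- channel_stack(dat, channel_names = c("copy", "scaled_copy"))
    attr(out, "similarity_scale") <- s
    out
  })
}
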