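# small shared helpers

# evaluate `expr` under a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fan a global seed out to per-module seeds; stays below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# block-average downscale of a matrix by integer factor f
block_downscale <- function(m, f) {
  if (f == 1L) return(m)
  h <- nrow(m); w <- ncol(m)
  stopifnot(h %% f == 0L, w %% f == 0L)
  a <- array(m, dim = c(f, h %/% f, f, w %/% f))
  apply(a, c(2L, 4L), mean)
}

# separable Gaussian blur (reflect boundary), used by phantom rendering and
# SSIM windows; kernel truncated at 3 sigma
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {
    n <- length(x)
    xp <- c(x[r:1], x, x[n:(n - r + 1L)])
    as.numeric(stats::filter(xp, k, sides = 2L))[(r + 1L):(r + n)]
  }
  m2 <- apply(m, 2L, conv1)
  t(apply(t(m2), 2L, conv1))
}

# reflect-pad a matrix to at least (H, W), centered
reflect_pad_to <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h >= H && w >= W) return(m)
  ry <- .reflect_index(h, H)
  rx <- .reflect_index(w, W)
  m[ry, rx, drop = FALSE]
}

.reflect_index <- function(n, N) {
  lead <- (N - n) %/% 2L
  idx <- seq_len(N) - lead
  period <- 2L * n
  idx <- ((idx - 1L) %% period) + 1L
  idx[idx > n] <- period - idx[idx > n] + 1L
  idx[idx < 1L] <- 1L - idx[idx < 1L]  # safety; cannot trigger for n >= 1
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
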