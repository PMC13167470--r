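#' Posterior sampling, MMSE estimation and tiled full-frame prediction
#'
#' The variational decoder yields a distribution over plausible splits of
#' an ambiguous input. Averaging `S` posterior samples pixel-wise
#' approximates the minimum mean-squared-error (MMSE) prediction; the
#' pixel-wise standard deviation over the same samples estimates the
#' pixel-wise RMSE of that prediction. Full frames are processed by inner
#' tiling: predictions are made on overlapping tiles but only each tile's
#' central region is kept, and the central regions partition the frame
#' exactly, suppressing edge artifacts.
#'
#' @name inference
NULL

#' Draw posterior samples for one input patch
#'
#' @param model a trained `vse_model`
#' @param lp an `lc_patch` (context levels must match the model config)
#' @param S number of posterior samples (>= 1); 50 is the reference
#'   protocol
#' @param seed RNG seed; fixed seed gives an identical sample set
#' @return a `posterior_sample_set`: list with `samples` (array
#'   `(h, w, k, S)`), `S`, `seed`
#' @export
sample_posterior <- function(model, lp, S = 50L, seed = 1L) {
  stopifnot(inherits(model, "vse_model"), S >= 1L)
  if (is.null(model$norm))
    stop("sample_posterior: model is untrained (no normalization statistics)")
  samples <- predict_tile(model, lp, S, seed)
  structure(list(samples = samples, S = as.integer(S),
                 seed = as.integer(seed)),
            class = "posterior_sample_set")
}

#' Predict S posterior samples for one patch (generic)
#'
#' S3 generic so that deterministic stand-in predictors can be used in
#' place of a trained network (e.g. for validating the tiling machinery).
#'
#' @param model predictor object
#' @param lp an `lc_patch`
#' @param S sample count
#' @param seed RNG seed
#' @return array `(h, w, k, S)` in raw intensity units
#' @export
predict_tile <- function(model, lp, S, seed) UseMethod("predict_tile")

#' @export
predict_tile.vse_model <- function(model, lp, S, seed) {
  enc <- encode(model, lc_batch(lp))
  h <- nrow(lp$primary); w <- ncol(lp$primary)
  k <- model$config$k_out
  out <- array(0, c(h, w, k, S))
  for (s in seq_len(S)) {
    dec <- decode_sample(model, enc, mode = "sample",
                         seed = derive_seed(seed, paste0("s", s)))
    out[, , , s] <- dec$pred[, , , 1L]
  }
  out
}

#' MMSE prediction and pixel-wise uncertainty from posterior samples
#'
#' @param samples a `posterior_sample_set` or an array `(h, w, k, S)`
#' @param calibration_scale optional multiplicative factor applied to the
#'   RMSE estimate (from [fit_calibration_scale()]); default 1
#' @return a `prediction_result`: `mmse` = pixel-wise sample mean,
#'   `rmse_estimate` = unbiased pixel-wise sample s.d. (requires `S >= 2`)
#' @export
mmse_and_uncertainty <- function(samples, calibration_scale = 1) {
  arr <- if (inherits(samples, "posterior_sample_set")) samples$samples
         else samples
  d <- dim(arr)
  S <- d[length(d)]
  if (S < 2L)
    stop("mmse_and_uncertainty: S >= 2 required for an uncertainty estimate")
  mmse <- apply(arr, seq_len(length(d) - 1L), mean)
  m2 <- apply(arr, seq_len(length(d) - 1L), function(v) sum((v - mean(v))^2))
  rmse <- calibration_scale * sqrt(m2 / (S - 1L))
  structure(list(mmse = mmse, rmse_estimate = rmse, S = S),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat("<prediction_result>", paste(dim(x$mmse), collapse = " x "),
      " (S =", x$S, ")\n")
  invisible(x)
}

# partition 1..n into write intervals whose prediction tiles have size
# `center`; last interval shifted inward so intervals tile exactly once
.tiling_starts <- function(n, center) {
  starts <- seq(1L, n - center + 1L, by = center)
  if (starts[length(starts)] + center - 1L < n)
    starts <- c(starts, n - center + 1L)
  starts
}

#' Inner-tiled full-frame prediction
#'
#' The frame is gridded so that the tiles' central regions cover every
#' output pixel exactly once (edge tiles are shifted inward). Per tile,
#' `S` posterior samples are drawn and averaged before stitching; the
#' pixel-wise sample s.d. provides the stitched RMSE estimate. Lateral
#' contexts are extracted around each tile's center from the full frame.
#' The reference geometry is 64-pixel tiles with 32-pixel centers and 50
#' samples.
#'
#' @param model a trained `vse_model` (or any object with a
#'   [predict_tile()] method and a `config$k_out`, `config$L`)
#' @param frame input image, matrix `H x W`
#' @param tile_size prediction patch side (even)
#' @param center_size retained central region side (even,
#'   `<= tile_size`)
#' @param S posterior samples per tile
#' @param seed RNG seed
#' @param calibration_scale factor applied to the RMSE estimate
#' @param retain_samples keep per-sample stitched frames (array
#'   `(H, W, k, S)`)
#' @param pad_small reflect-pad frames smaller than one tile (otherwise
#'   error)
#' @return a `prediction_result` with full-frame `mmse` and
#'   `rmse_estimate` (`(H, W, k)`); attribute `coverage` holds the
#'   write-count map (all ones by construction)
#' @export
tiled_predict <- function(model, frame, tile_size = 64L, center_size = 32L,
                          S = 50L, seed = 1L, calibration_scale = 1,
                          retain_samples = FALSE, pad_small = TRUE) {
  stopifnot(tile_size %% 2L == 0L, center_size %% 2L == 0L,
            center_size <= tile_size)
  H <- nrow(frame); W <- ncol(frame)
  if (H < tile_size || W < tile_size) {
    if (!pad_small)
      stop("tiled_predict: frame smaller than one tile")
    fr2 <- reflect_pad_to(frame, max(H, tile_size), max(W, tile_size))
    res <- tiled_predict(model, fr2, tile_size, center_size, S, seed,
                         calibration_scale, retain_samples,
                         pad_small = FALSE)
    oy <- (nrow(fr2) - H) %/% 2L; ox <- (ncol(fr2) - W) %/% 2L
    res$mmse <- res$mmse[(oy + 1L):(oy + H), (ox + 1L):(ox + W), , drop = FALSE]
    res$rmse_estimate <- res$rmse_estimate[(oy + 1L):(oy + H),
                                           (ox + 1L):(ox + W), , drop = FALSE]
    return(res)
  }
  k <- model$config$k_out
  L <- model$config$L
  margin <- (tile_size - center_size) %/% 2L
  ys <- .tiling_starts(H, center_size)
  xs <- .tiling_starts(W, center_size)
  mmse <- array(0, c(H, W, k))
  rmse <- array(0, c(H, W, k))
  coverage <- matrix(0L, H, W)
  keep <- if (retain_samples) array(0, c(H, W, k, S))
  prev_y_end <- 0L
  ti <- 0L
  for (iy in seq_along(ys)) {
    cy1 <- ys[iy]; cy2 <- cy1 + center_size - 1L
    wy1 <- max(cy1, prev_y_end + 1L); wy2 <- cy2
    prev_y_end <- cy2
    prev_x_end <- 0L
    for (ix in seq_along(xs)) {
      ti <- ti + 1L
      cx1 <- xs[ix]; cx2 <- cx1 + center_size - 1L
      wx1 <- max(cx1, prev_x_end + 1L); wx2 <- cx2
      prev_x_end <- cx2
      # tile window around the center region, shifted inward at borders
      ty1 <- min(max(cy1 - margin, 1L), H - tile_size + 1L)
      tx1 <- min(max(cx1 - margin, 1L), W - tile_size + 1L)
      tcy <- ty1 + tile_size %/% 2L - 1L
      tcx <- tx1 + tile_size %/% 2L - 1L
      lp <- extract_lc_patch(frame, c(tcy, tcx), tile_size, L)
      smp <- predict_tile(model, lp, S, derive_seed(seed, paste0("t", ti)))
      # rows of the write region inside the tile
      ry <- (wy1:wy2) - ty1 + 1L
      rx <- (wx1:wx2) - tx1 + 1L
      tile_mean <- apply(smp, c(1L, 2L, 3L), mean)
      mmse[wy1:wy2, wx1:wx2, ] <- tile_mean[ry, rx, , drop = FALSE]
      if (S >= 2L) {
        tile_sd <- sqrt(apply(smp, c(1L, 2L, 3L), stats::var))
        rmse[wy1:wy2, wx1:wx2, ] <-
          calibration_scale * tile_sd[ry, rx, , drop = FALSE]
      }
      if (retain_samples)
        keep[wy1:wy2, wx1:wx2, , ] <- smp[ry, rx, , , drop = FALSE]
      coverage[wy1:wy2, wx1:wx2] <- coverage[wy1:wy2, wx1:wx2] + 1L
    }
  }
  out <- structure(list(mmse = mmse, rmse_estimate = rmse, S = S),
                   class = "prediction_result")
  if (retain_samples) out$samples <- keep
  attr(out, "coverage") <- coverage
  out
}
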