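#' Range-invariant PSNR for microscopy predictions
#'
#' Predictions of intensity up to an affine transform are standard in
#' content-aware restoration, so the prediction is first fitted to the
#' reference by ordinary least squares (`a * pred + b`), and the PSNR is
#' computed from the post-fit residual with the reference dynamic range
#' (`max - min`). The value is therefore invariant to affine transforms of
#' the prediction. A perfect match is capped at 100 dB.
#'
#' @param pred prediction, any numeric array
#' @param reference ground-truth reference, same length; must be
#'   non-constant
#' @return PSNR in dB
#' @export
care_psnr <- function(pred, reference) {
  p <- as.numeric(pred); r <- as.numeric(reference)
  stopifnot(length(p) == length(r))
  if (stats::sd(r) < 1e-12) stop("care_psnr: constant reference")
  fit <- stats::lm.fit(cbind(1, p), r)
  res <- fit$residuals
  mse <- mean(res^2)
  rng <- max(r) - min(r)
  if (mse < (rng * 1e-10)^2) return(100)
  min(20 * log10(rng / sqrt(mse)), 100)
}

# single-scale SSIM map mean with Gaussian windows
.ssim_scale <- function(x, y, rng, sigma = 1.5) {
  c1 <- (0.01 * rng)^2; c2 <- (0.03 * rng)^2
  mx <- gauss_blur(x, sigma); my <- gauss_blur(y, sigma)
  sxx <- gauss_blur(x * x, sigma) - mx * mx
  syy <- gauss_blur(y * y, sigma) - my * my
  sxy <- gauss_blur(x * y, sigma) - mx * my
  num <- (2 * mx * my + c1) * (2 * sxy + c2)
  den <- (mx * mx + my * my + c1) * (sxx + syy + c2)
  mean(num / den)
}

#' Multi-scale SSIM adapted for microscopy intensity conventions
#'
#' Structural similarity computed after (1) subtracting the reference's
#' 1st-percentile background and (2) least-squares affine normalization of
#' the prediction to the reference, making the metric invariant to affine
#' transforms of the prediction. SSIM is evaluated with Gaussian windows
#' (s.d. 1.5 px) at `n_scales` dyadic scales (block-average downsampling)
#' and the per-scale values are averaged with equal weights; the result is
#' clamped to `[0, 1]`.
#'
#' @param pred prediction, matrix or array (flattened per 2D plane is the
#'   caller's responsibility; matrices expected)
#' @param reference reference, same dimensions
#' @param n_scales number of dyadic scales (default 3)
#' @return value in `[0, 1]`; 1 for `pred` equal to an affine transform of
#'   `reference`
#' @export
micro_ms_ssim <- function(pred, reference, n_scales = 3L) {
  stopifnot(is.matrix(pred), is.matrix(reference),
            all(dim(pred) == dim(reference)))
  min_side <- 8L * 2L^(n_scales - 1L)
  if (min(dim(pred)) < min_side)
    stop("micro_ms_ssim: image too small for ", n_scales, "-scale pyramid")
  bg <- stats::quantile(reference, 0.01, names = FALSE)
  r <- reference - bg
  fit <- stats::lm.fit(cbind(1, as.numeric(pred)), as.numeric(r))
  p <- matrix(fit$coefficients[2L] * as.numeric(pred) + fit$coefficients[1L],
              nrow(pred))
  vals <- numeric(n_scales)
  for (s in seq_len(n_scales)) {
    rng <- max(r) - min(r)
    if (rng < 1e-12) stop("micro_ms_ssim: constant reference")
    vals[s] <- .ssim_scale(p, r, rng)
    if (s < n_scales) {
      h <- 2L * (nrow(p) %/% 2L); w <- 2L * (ncol(p) %/% 2L)
      p <- block_downscale(p[seq_len(h), seq_len(w), drop = FALSE], 2L)
      r <- block_downscale(r[seq_len(h), seq_len(w), drop = FALSE], 2L)
    }
  }
  min(max(mean(vals), 0), 1)
}

#' Calibration analysis: does predicted uncertainty track true error?
#'
#' Pixels are binned by quantiles of the predicted uncertainty. Per bin,
#' RMV (root mean predicted variance) summarizes what the model believes
#' its error is, and RMSE (root mean squared error of the MMSE prediction
#' against the reference) measures the actual error. For a calibrated
#' model the bin points lie on the identity: slope about 1 and strongly
#' positive rank correlation.
#'
#' @param rmse_estimate pixel-wise predicted uncertainty (posterior sample
#'   s.d.), any array
#' @param mmse MMSE prediction, same shape
#' @param reference ground-truth reference, same shape
#' @param n_bins number of quantile bins (>= 3)
#' @return a `calibration_curve`: data.frame `bins` (rmv, rmse, count,
#'   bin edges), `slope` (least squares through the bin points),
#'   `rank_correlation` (Spearman), `degenerate` flag (set when the
#'   uncertainty has too few distinct values to bin)
#' @export
calibration_analysis <- function(rmse_estimate, mmse, reference,
                                 n_bins = 20L) {
  if (is.null(reference)) stop("calibration_analysis: reference missing")
  stopifnot(n_bins >= 3L)
  u <- as.numeric(rmse_estimate)
  e2 <- (as.numeric(mmse) - as.numeric(reference))^2
  stopifnot(length(u) == length(e2))
  qs <- stats::quantile(u, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE)
  qs <- unique(qs)
  if (length(qs) < 4L) {
    bins <- data.frame(rmv = sqrt(mean(u^2)), rmse = sqrt(mean(e2)),
                       count = length(u))
    return(structure(list(bins = bins, slope = NA_real_,
                          rank_correlation = NA_real_, degenerate = TRUE),
                     class = "calibration_curve"))
  }
  qs[1L] <- qs[1L] - 1e-12
  bin <- cut(u, qs, labels = FALSE)
  rmv <- sqrt(tapply(u^2, bin, mean))
  rmse <- sqrt(tapply(e2, bin, mean))
  count <- as.integer(table(bin))
  bins <- data.frame(rmv = as.numeric(rmv), rmse = as.numeric(rmse),
                     count = count,
                     lo = qs[-length(qs)], hi = qs[-1L])
  fit <- stats::lm.fit(cbind(1, bins$rmv), bins$rmse)
  structure(list(bins = bins,
                 slope = unname(fit$coefficients[2L]),
                 rank_correlation = stats::cor(bins$rmv, bins$rmse,
                                               method = "spearman"),
                 degenerate = FALSE),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  if (x$degenerate) {
    cat("<calibration_curve> degenerate (constant uncertainty)\n")
  } else {
    cat("<calibration_curve>", nrow(x$bins), "bins, slope",
        format(x$slope, digits = 3), ", rank correlation",
        format(x$rank_correlation, digits = 3), "\n")
  }
  invisible(x)
}

#' @export
plot.calibration_curve <- function(x, ...) {
  if (x$degenerate) stop("cannot plot a degenerate calibration curve")
  graphics::plot(x$bins$rmv, x$bins$rmse, xlab = "RMV (predicted)",
                 ylab = "RMSE (true)", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(stats::lm(rmse ~ rmv, data = x$bins), col = 2)
  invisible(x)
}

#' Fit a multiplicative calibration factor
#'
#' Least-squares scalar minimizing `sum((RMSE_bin - factor * RMV_bin)^2)`
#' over the calibration bins; applied multiplicatively to downstream
#' uncertainty estimates when enabled.
#'
#' @inheritParams calibration_analysis
#' @return scalar factor
#' @export
fit_calibration_scale <- function(rmse_estimate, mmse, reference,
                                  n_bins = 20L) {
  cc <- calibration_analysis(rmse_estimate, mmse, reference, n_bins)
  if (cc$degenerate || sum(cc$bins$rmv^2) < 1e-20)
    stop("fit_calibration_scale: degenerate bins (no uncertainty spread)")
  sum(cc$bins$rmse * cc$bins$rmv) / sum(cc$bins$rmv^2)
}
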