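#' Pixel-wise observation-likelihood noise models
#'
#' A noise model describes `p(noisy observation | clean signal)` for every
#' pixel. During training it lets the network place likelihood on noisy
#' targets while predicting clean signal, which is what makes unsupervised
#' denoising work: the supervised targets may be noisy, yet the minimizer of
#' the expected likelihood is the clean signal.
#'
#' Three families are provided:
#' * `"gaussian"` -- additive read noise, `obs ~ N(signal, sigma^2)`.
#' * `"pg"` -- analytic Poisson-Gaussian: `obs ~ N(signal, a*signal + b^2)`
#'   (the standard Gaussian approximation of shot plus read noise, with
#'   photon-conversion factor `a` and read-noise s.d. `b`).
#' * `"gmm"` -- a Gaussian mixture over the residual `obs - signal`, whose
#'   component standard deviations may vary with the signal level through a
#'   polynomial; fitted from co-registered calibration pairs with
#'   [fit_noise_model()].
#'
#' @name noise_models
NULL

#' @param sigma read-noise standard deviation (> 0)
#' @param signal_range intensity interval the model is valid on; signals
#'   outside are clamped before evaluation
#' @return an object of class `noise_model`
#' @rdname noise_models
#' @export
gaussian_noise_model <- function(sigma, signal_range = c(-Inf, Inf)) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  structure(list(kind = "gaussian", sigma = sigma,
                 signal_range = signal_range),
            class = "noise_model")
}

#' @param poisson_scale photon-conversion factor `a` (>= 0); the shot-noise
#'   variance contribution is `a * signal`
#' @param gaussian_sigma read-noise s.d. `b` (>= 0); `a` and `b` must not
#'   both be zero
#' @rdname noise_models
#' @export
pg_noise_model <- function(poisson_scale, gaussian_sigma,
                           signal_range = c(-Inf, Inf)) {
  stopifnot(poisson_scale >= 0, gaussian_sigma >= 0,
            poisson_scale + gaussian_sigma > 0)
  structure(list(kind = "pg", a = poisson_scale, b = gaussian_sigma,
                 signal_range = signal_range),
            class = "noise_model")
}

.nm_clamp_signal <- function(model, signal) {
  lo <- model$signal_range[1L]; hi <- model$signal_range[2L]
  pmin(pmax(signal, lo), hi)
}

.polyval <- function(coef, t) {
  # coef[1] + coef[2]*t + ... ; vectorized over t
  out <- rep(coef[length(coef)], length(t))
  if (length(coef) > 1L)
    for (j in seq(length(coef) - 1L, 1L)) out <- out * t + coef[j]
  out
}

.polyderiv <- function(coef) {
  if (length(coef) <= 1L) return(0)
  coef[-1L] * seq_len(length(coef) - 1L)
}

.gmm_t <- function(model, s) {
  # map signal into the normalized coordinate the polynomials are fit in
  (s - model$t_center) / model$t_scale
}

.gmm_component_params <- function(model, s) {
  t <- .gmm_t(model, s)
  k <- length(model$weights)
  sds <- matrix(0, length(s), k)
  for (c in seq_len(k)) sds[, c] <- exp(.polyval(model$log_sd_coef[[c]], t))
  list(t = t, sds = sds)
}

#' Per-pixel log-likelihood of noisy observations given clean signal
#'
#' @param model a `noise_model`
#' @param observation numeric array of noisy pixel values
#' @param signal numeric array of clean signal values, same shape
#' @return array of per-pixel log-densities, same shape as `observation`
#' @export
noise_loglikelihood <- function(model, observation, signal) {
  stopifnot(inherits(model, "noise_model"))
  if (anyNA(observation) || anyNA(signal))
    stop("noise_loglikelihood: NA/NaN in inputs")
  if (length(observation) != length(signal))
    stop("noise_loglikelihood: observation and signal shapes differ")
  out <- noise_loglik_grad(model, observation, signal)$loglik
  if (is.array(observation)) array(out, dim(observation)) else out
}

# log-likelihood and its derivative with respect to the clean signal;
# internal, used by the training graph. Signals outside signal_range are
# clamped; the gradient is evaluated at the clamped point (straight
# through), so the denoising branch keeps pulling out-of-range
# predictions back instead of going silent.
noise_loglik_grad <- function(model, observation, signal) {
  o <- as.numeric(observation)
  s_raw <- as.numeric(signal)
  s <- .nm_clamp_signal(model, s_raw)
  if (model$kind == "gaussian") {
    v <- model$sigma^2
    r <- o - s
    ll <- -0.5 * log(2 * pi * v) - r * r / (2 * v)
    ds <- r / v
  } else if (model$kind == "pg") {
    se <- pmax(s, 1e-12)
    v <- model$a * se + model$b^2
    v <- pmax(v, 1e-12)
    r <- o - s
    ll <- -0.5 * log(2 * pi * v) - r * r / (2 * v)
    ds <- r / v + model$a * (-0.5 / v + r * r / (2 * v * v)) * (s > 0)
  } else if (model$kind == "gmm") {
    k <- length(model$weights)
    pars <- .gmm_component_params(model, s)
    r <- o - s
    comp_log <- matrix(0, length(o), k)
    for (c in seq_len(k))
      comp_log[, c] <- log(model$weights[c]) +
        stats::dnorm(r, mean = model$means[c], sd = pars$sds[, c], log = TRUE)
    m <- apply(comp_log, 1L, max)
    ll <- m + log(rowSums(exp(comp_log - m)))
    resp <- exp(comp_log - ll)
    ds <- numeric(length(o))
    for (c in seq_len(k)) {
      mu <- s + model$means[c]
      sd <- pars$sds[, c]
      dsd_ds <- sd * .polyval(.polyderiv(model$log_sd_coef[[c]]), pars$t) /
        model$t_scale
      dll_c <- (o - mu) / sd^2 +
        ((o - mu)^2 / sd^3 - 1 / sd) * dsd_ds
      ds <- ds + resp[, c] * dll_c
    }
  } else stop("unknown noise model kind: ", model$kind)
  dm <- if (!is.null(dim(observation))) dim(observation) else NULL
  list(loglik = if (is.null(dm)) ll else array(ll, dm),
       dsignal = if (is.null(dm)) ds else array(ds, dm))
}

#' Fit a Gaussian-mixture noise model from calibration image pairs
#'
#' Expects co-registered pairs of a low-noise reference (taken as the clean
#' signal) and a noisy acquisition of the same field. The mixture is fitted
#' to the residuals `observation - signal` by expectation-maximization;
#' with `degree > 0` the component standard deviations become polynomial
#' functions of the signal level (fitted across signal bins).
#'
#' @param signal clean/low-noise reference pixel values
#' @param observation noisy pixel values, same shape
#' @param n_components number of mixture components (>= 1)
#' @param degree polynomial degree for the signal dependence of the
#'   component standard deviations (0 = signal-independent)
#' @param max_iter EM iteration budget
#' @param n_bins signal bins used when `degree > 0`
#' @param seed seed for the EM initialization
#' @return a `noise_model` of kind `"gmm"` with `signal_range` set from the
#'   0.1/99.9 signal percentiles
#' @export
fit_noise_model <- function(signal, observation, n_components = 1L,
                            degree = 0L, max_iter = 200L, n_bins = 12L,
                            seed = 1L) {
  stopifnot(n_components >= 1L, degree >= 0L)
  s <- as.numeric(signal); o <- as.numeric(observation)
  if (length(s) != length(o)) stop("fit_noise_model: shape mismatch")
  if (anyNA(s) || anyNA(o)) stop("fit_noise_model: NA in calibration pairs")
  r <- o - s
  if (stats::sd(r) < 1e-8)
    stop("fit_noise_model: degenerate calibration pairs (zero residual spread)")
  if (stats::sd(s) < 1e-12 && degree > 0L)
    stop("fit_noise_model: constant signal cannot constrain signal dependence")
  sr <- stats::quantile(s, c(0.001, 0.999), names = FALSE)
  t_center <- mean(sr)
  t_scale <- max((sr[2L] - sr[1L]) / 2, 1e-12)
  k <- n_components

  with_seed(seed, {
    # initialize component s.d.s spread across the residual scale
    sd0 <- stats::sd(r) * 2^(seq_len(k) - (k + 1) / 2)
    mu0 <- rep(0, k)
    w0 <- rep(1 / k, k)
    mod <- list(w = w0, mu = mu0, sd = matrix(sd0, 1L, k))
    tmid <- 0
    if (degree > 0L) {
      qs <- stats::quantile(s, probs = seq(0, 1, length.out = n_bins + 1L),
                            names = FALSE)
      qs[1L] <- qs[1L] - 1e-9
      bin <- cut(s, qs, labels = FALSE)
      tmid <- (qs[-1L] + qs[-length(qs)]) / 2
      tmid <- (tmid - t_center) / t_scale
    } else {
      bin <- rep(1L, length(r))
      n_bins <- 1L
    }
    sd_pix <- matrix(rep(sd0, each = length(r)), ncol = k)
    mu <- mu0; w <- w0
    ll_old <- -Inf
    coef <- lapply(seq_len(k), function(c) c(log(sd0[c]), rep(0, degree)))
    for (it in seq_len(max_iter)) {
      comp_log <- matrix(0, length(r), k)
      for (c in seq_len(k))
        comp_log[, c] <- log(w[c]) +
          stats::dnorm(r, mu[c], sd_pix[, c], log = TRUE)
      mrow <- apply(comp_log, 1L, max)
      lse <- mrow + log(rowSums(exp(comp_log - mrow)))
      resp <- exp(comp_log - lse)
      ll <- mean(lse)
      if (is.finite(ll_old) && abs(ll - ll_old) < 1e-9) break
      ll_old <- ll
      # M-step
      nk <- colSums(resp)
      w <- nk / sum(nk)
      for (c in seq_len(k)) {
        mu[c] <- sum(resp[, c] * r) / nk[c]
        if (degree == 0L) {
          sdc <- sqrt(sum(resp[, c] * (r - mu[c])^2) / nk[c])
          sdc <- max(sdc, 1e-10)
          coef[[c]] <- log(sdc)
          sd_pix[, c] <- sdc
        } else {
          # per-bin weighted s.d., then polynomial fit of log s.d.
          num <- tapply(resp[, c] * (r - mu[c])^2, bin, sum)
          den <- tapply(resp[, c], bin, sum)
          keep <- which(den > 1e-8)
          lsd <- as.numeric(0.5 * log(pmax(num[keep] / den[keep], 1e-20)))
          X <- stats::poly(tmid[keep], degree = degree, raw = TRUE)
          fit <- stats::lm.wfit(cbind(1, X), lsd, w = as.numeric(den[keep]))
          coef[[c]] <- unname(fit$coefficients)
          tpix <- (s - t_center) / t_scale
          sd_pix[, c] <- exp(.polyval(coef[[c]], tpix))
        }
      }
    }
    structure(list(kind = "gmm",
                   weights = as.numeric(w),
                   means = as.numeric(mu),
                   log_sd_coef = coef,
                   t_center = t_center, t_scale = t_scale,
                   signal_range = sr,
                   loglik = ll_old,
                   n_iter = it),
              class = "noise_model")
  })
}

#' Serialize / deserialize a noise model
#'
#' Models are written as a single versioned JSON file.
#'
#' @param model a `noise_model`
#' @param path file path
#' @export
write_noise_model <- function(model, path) {
  stopifnot(inherits(model, "noise_model"))
  obj <- unclass(model)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  if (!is.null(obj$log_sd_coef))
    obj$log_sd_coef <- lapply(obj$log_sd_coef, as.numeric)
  if (!is.null(obj$signal_range)) obj$signal_range <- as.numeric(obj$signal_range)
  structure(obj, class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model>", x$kind)
  if (x$kind == "gaussian") cat("  sigma =", format(x$sigma))
  if (x$kind == "pg") cat("  a =", format(x$a), " b =", format(x$b))
  if (x$kind == "gmm") cat("  components =", length(x$weights))
  cat("\n  signal_range: [", paste(format(x$signal_range), collapse = ", "),
      "]\n")
  invisible(x)
}
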