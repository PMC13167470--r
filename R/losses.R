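#' Loss configuration for the joint split-and-denoise objective
#'
#' The training loss is the weighted average of two branches,
#' `loss = w * loss_denoise + (1 - w) * loss_direct`, where the denoising
#' branch scores the noisy targets under a pixel noise model applied to the
#' predicted clean signal, and the direct branch is a Gaussian likelihood
#' of the targets under the predicted means (with learned or fixed
#' variance). Both branches share the same KL terms, one per hierarchy
#' level, each center-cropped to the spatial shape the latent tensor would
#' have without lateral-context inputs (so that activating context does
#' not inflate the KL weight), and scaled by `alpha`.
#'
#' @param w branch weight in `[0, 1]`; `w = 1` is the pure
#'   noise-model-denoising objective, `w = 0` the pure direct-likelihood
#'   objective; 0.9 is the default used throughout
#' @param alpha KL weight; `NULL` (default) uses `1 / n_pixels` of the
#'   cropped latent shape at each level, keeping the KL/likelihood balance
#'   independent of patch size
#' @param kl_free_nats optional per-level floor subtracted from the KL
#'   (clamped at 0); 0 matches the printed objective
#' @param likelihood_variance_mode `"learned"` per-pixel log-variance from
#'   the head, or `"fixed"`
#' @param fixed_sigma s.d. used when `likelihood_variance_mode = "fixed"`
#'   (normalized intensity units)
#' @export
loss_config <- function(w = 0.9, alpha = NULL, kl_free_nats = 0,
                        likelihood_variance_mode = c("learned", "fixed"),
                        fixed_sigma = 1) {
  likelihood_variance_mode <- match.arg(likelihood_variance_mode)
  stopifnot(w >= 0, w <= 1, is.null(alpha) || alpha > 0, kl_free_nats >= 0)
  structure(list(w = w, alpha = alpha, kl_free_nats = kl_free_nats,
                 likelihood_variance_mode = likelihood_variance_mode,
                 fixed_sigma = fixed_sigma),
            class = "loss_config")
}

#' Pixel-wise KL divergence per hierarchy level
#'
#' Closed-form KL between diagonal Gaussians,
#' `KL(N(mu_q, e^lv_q) || N(mu_p, e^lv_p))`, evaluated pixel-wise.
#'
#' @param latents list with one entry per hierarchy level, each a list with
#'   arrays `mu_q`, `lv_q`, `mu_p`, `lv_p` of identical shape
#' @return list of non-negative arrays, one per level
#' @export
kl_per_level <- function(latents) {
  lapply(latents, function(l) {
    if (length(l$mu_q) != length(l$mu_p) ||
        length(l$lv_q) != length(l$lv_p))
      stop("kl_per_level: posterior/prior shape mismatch")
    vq <- exp(l$lv_q); vp <- exp(l$lv_p)
    dm <- l$mu_q - l$mu_p
    0.5 * (l$lv_p - l$lv_q + (vq + dm * dm) / vp - 1)
  })
}

# center-crop the trailing two dims of an array (C, H, W) to (h, w);
# for odd margins the extra pixel is dropped from the trailing side
.crop_chw <- function(KL, h, w) {
  d <- dim(KL)
  H <- d[length(d) - 1L]; W <- d[length(d)]
  if (h > H || w > W) stop("kl crop target larger than source")
  oy <- (H - h) %/% 2L; ox <- (W - w) %/% 2L
  if (length(d) == 3L) KL[, (oy + 1L):(oy + h), (ox + 1L):(ox + w),
                          drop = FALSE]
  else KL[, , (oy + 1L):(oy + h), (ox + 1L):(ox + w), drop = FALSE]
}

#' Center-cropped KL loss for one hierarchy level
#'
#' With lateral-context inputs the latent tensors keep the primary patch's
#' spatial size, so a plain sum over pixels would grow with the number of
#' summands and overweight the KL against the likelihood. The pixel-wise
#' KL is therefore center-cropped to the shape it would assume without
#' context inputs before summation.
#'
#' @param KL pixel-wise KL array `(C, H, W)`
#' @param target_shape spatial crop target `c(h, w)`; equal to `dim(KL)[2:3]`
#'   reproduces the uncropped sum exactly
#' @param alpha KL weight multiplier
#' @return scalar `alpha * sum(cropped KL)`
#' @export
kl_loss_cropped <- function(KL, target_shape, alpha = 1) {
  stopifnot(length(dim(KL)) == 3L, length(target_shape) == 2L)
  alpha * sum(.crop_chw(KL, target_shape[1L], target_shape[2L]))
}

#' Volumetric KL loss with z-averaging
#'
#' For volumetric data the pixel-wise KL is a `(C, Z, H, W)` tensor; naive
#' summation would grow with the number of z-slices, overweighting the KL
#' as more input planes are added. The tensor is first averaged along z,
#' and the resulting `(C, H, W)` tensor is passed to the center-cropped
#' sum, making the scalar invariant to replication along z.
#'
#' @param KL pixel-wise KL array `(C, Z, H, W)`
#' @param target_shape spatial crop target `c(h, w)`
#' @param alpha KL weight multiplier
#' @return scalar
#' @export
kl_loss_3d <- function(KL, target_shape, alpha = 1) {
  stopifnot(length(dim(KL)) == 4L)
  zm <- apply(KL, c(1L, 3L, 4L), mean)
  kl_loss_cropped(zm, target_shape, alpha)
}

#' Direct (Gaussian) reconstruction negative log-likelihood
#'
#' Gaussian negative log-likelihood of the noisy targets under the
#' predicted per-pixel means, summed over channels and pixels. With
#' `pred_logvar = NULL` the variance is fixed at `sigma^2` and the value
#' reduces to `sum(r^2) / (2 sigma^2)` plus a constant.
#'
#' @param pred_mu predicted means, any array
#' @param target targets, same shape
#' @param pred_logvar optional learned per-pixel log-variance, same shape
#' @param sigma fixed s.d. used when `pred_logvar` is `NULL`
#' @return scalar negative log-likelihood
#' @export
musplit_likelihood <- function(pred_mu, target, pred_logvar = NULL,
                               sigma = 1) {
  if (!all(is.finite(pred_mu))) stop("musplit_likelihood: non-finite prediction")
  stopifnot(length(pred_mu) == length(target))
  lv <- if (is.null(pred_logvar)) 2 * log(sigma) else pred_logvar
  r <- target - pred_mu
  sum(0.5 * (log(2 * pi) + lv + r * r / exp(lv)))
}

#' Noise-model (denoising) negative log-likelihood
#'
#' Scores the noisy targets under the noise model evaluated at the
#' predicted clean signal: `-sum(log p(target | prediction))`. Because the
#' model separates signal from noise, the minimizer is the clean signal
#' even though only noisy targets are observed.
#'
#' @param pred predicted clean signal, any array
#' @param target noisy targets, same shape
#' @param model a `noise_model`
#' @return scalar negative log-likelihood
#' @export
denoisplit_likelihood <- function(pred, target, model) {
  if (is.null(model)) stop("denoisplit_likelihood: missing noise model")
  -sum(noise_loglikelihood(model, target, pred))
}

#' Combined split-and-denoise training objective (array form)
#'
#' `loss = w * (nll_noise + kl) + (1 - w) * (nll_direct + kl)`, with the
#' same per-level center-cropped KL entering both branches; affine in `w`.
#'
#' @param pred_mu predicted channel means (raw intensity units)
#' @param targets noisy targets, same shape
#' @param latents per-level posterior/prior parameter arrays (see
#'   [kl_per_level()]); each level's entry additionally carries
#'   `no_lc_shape = c(h, w)`, the crop target
#' @param noise_model a `noise_model` for the denoising branch
#' @param cfg a [loss_config()]
#' @param pred_logvar optional learned log-variance for the direct branch
#' @return list with `loss` and a `terms` breakdown (`nll_denoise`,
#'   `nll_direct`, `kl` per level and total)
#' @export
microsplit_loss <- function(pred_mu, targets, latents, noise_model, cfg,
                            pred_logvar = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  kls <- kl_per_level(latents)
  kl_terms <- vapply(seq_along(kls), function(i) {
    shp <- latents[[i]]$no_lc_shape
    a <- cfg$alpha %||% (1 / prod(shp))
    v <- if (length(dim(kls[[i]])) == 4L) kl_loss_3d(kls[[i]], shp, a)
         else kl_loss_cropped(kls[[i]], shp, a)
    max(v - cfg$kl_free_nats, 0)
  }, 0)
  nll_d <- if (cfg$w > 0) denoisplit_likelihood(pred_mu, targets, noise_model)
           else 0
  nll_m <- if (cfg$w < 1)
    musplit_likelihood(pred_mu, targets,
                       if (cfg$likelihood_variance_mode == "learned")
                         pred_logvar, cfg$fixed_sigma)
    else 0
  loss <- cfg$w * nll_d + (1 - cfg$w) * nll_m + sum(kl_terms)
  list(loss = loss,
       terms = list(nll_denoise = nll_d, nll_direct = nll_m,
                    kl = sum(kl_terms), kl_levels = kl_terms))
}

# ---- graph-side loss (training path) ---------------------------------------
#
# Builds the differentiable loss on an encoding + decode graph. The
# denoising branch is evaluated in raw intensity units (predictions are
# de-normalized channel-wise), the direct branch in normalized units.
# KL is computed per batch element and averaged; nz > 1 signals z-slices
# folded into the batch axis, triggering the z-averaged volumetric KL.
# Likelihood terms are normalized per pixel (per batch element) so that
# the per-pixel-normalized KL and the likelihood sit on comparable
# scales regardless of patch size; this is a monotone rescaling of the
# summed objective and does not change its minimizers.
.loss_graph <- function(model, enc, dec, batch, noise_model, cfg, nz = 1L,
                        kl_scale = 1) {
  tape <- enc$tape
  cfgm <- model$config
  nm <- model$norm
  nb <- enc$input$nb
  nvol <- nb %/% nz
  k <- cfgm$k_out
  hw <- enc$input$h * enc$input$w
  # targets as (nb*hw) x k matrices
  tg_raw <- matrix(0, nb * hw, k)
  for (c in seq_len(k)) tg_raw[, c] <- as.vector(batch$targets[, , c, ])
  tg_norm <- sweep(sweep(tg_raw, 2L, nm$t_mean, "-"), 2L, nm$t_sd, "/")

  kl_total <- NULL
  kl_vals <- numeric(cfgm$hierarchy_levels)
  for (i in seq_len(cfgm$hierarchy_levels)) {
    l <- dec$latents[[i]]
    klpx <- ad_kl_diag(tape, l$mu_q, l$lv_q, l$mu_p, l$lv_p)
    if (nz > 1L) klpx <- ad_zmean(tape, klpx, nz)
    s_nolc <- .level_size_no_lc(cfgm, i)
    klpx <- ad_crop_center(tape, klpx, s_nolc, s_nolc)
    a <- kl_scale * (cfg$alpha %||% (1 / (s_nolc * s_nolc)))
    kl_i <- ad_scale(tape, ad_sum(tape, klpx), a / nvol)
    kl_vals[i] <- kl_i$val[1L]
    kl_total <- if (is.null(kl_total)) kl_i else ad_add(tape, kl_total, kl_i)
  }

  terms <- list(kl = sum(kl_vals), kl_levels = kl_vals)
  loss <- kl_total
  nb_eff <- max(nvol, 1L) * hw
  if (cfg$w > 0) {
    if (is.null(noise_model))
      stop("loss: denoising branch active (w > 0) but no noise model given")
    pred_raw <- ad_affine_cols(tape, dec$pred_mu, nm$t_sd, nm$t_mean)
    nll_d_px <- ad_noise_nll(tape, pred_raw, tg_raw, noise_model)
    nll_d <- ad_scale(tape, ad_sum(tape, nll_d_px), 1 / nb_eff)
    terms$nll_denoise <- nll_d$val[1L]
    loss <- ad_add(tape, loss, ad_scale(tape, nll_d, cfg$w))
  }
  if (cfg$w < 1) {
    lv <- if (cfg$likelihood_variance_mode == "learned") dec$pred_lv
          else ad_const(tape,
                        matrix(2 * log(cfg$fixed_sigma), nb * hw, k),
                        n = nb, h = enc$input$h, w = enc$input$w)
    nll_m_px <- ad_gauss_nll(tape, dec$pred_mu, lv, tg_norm)
    nll_m <- ad_scale(tape, ad_sum(tape, nll_m_px), 1 / nb_eff)
    terms$nll_direct <- nll_m$val[1L]
    loss <- ad_add(tape, loss, ad_scale(tape, nll_m, 1 - cfg$w))
  }
  if (!is.finite(loss$val[1L])) {
    bad <- names(Filter(function(v) !is.finite(v),
                        list(kl = terms$kl,
                             nll_denoise = terms$nll_denoise %||% 0,
                             nll_direct = terms$nll_direct %||% 0)))
    stop("loss: non-finite value in term(s): ", paste(bad, collapse = ", "))
  }
  list(loss = loss, terms = terms)
}
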