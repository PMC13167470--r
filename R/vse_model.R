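#' Model configuration for the variational splitting encoder-decoder
#'
#' The network is a hierarchical variational encoder-decoder (ladder-VAE
#' style) that is not an autoencoder: it maps one superimposed input
#' channel to `k_out` structure channels. The bottom-up encoder pools the
#' primary-patch features at every hierarchy level; with lateral context
#' active, pooled features are zero-padded back to the primary dimensions
#' and concatenated with the output of a dedicated, pooling-free input
#' branch that digests the matching context patch, so merged feature maps
#' retain the primary patch's spatial dimensions throughout the hierarchy.
#' The top-down decoder carries a conditional prior per level, samples
#' latents from the inferred posterior, and ends in a head predicting
#' per-channel pixel means and log-variances.
#'
#' @param k_out number of output structure channels
#' @param hierarchy_levels number of stochastic hierarchy levels (>= 2)
#' @param base_filters convolutional width
#' @param L lateral-context levels (`L <= hierarchy_levels - 1`); the
#'   deep-context default of the full-scale method is `L = 2`
#'   (`multiscale_lowres_count = 3`)
#' @param z_channels latent channels per level
#' @param variant `"lean_lc"` (single conv per block) or `"deep_lc"`
#'   (extra convs in input branches and top-down blocks)
#' @param dims 2 for planar data, 3 for volumetric data (convolutions are
#'   applied per z-slice with shared weights; the volumetric KL treatment
#'   happens in the loss)
#' @param patch_size primary patch side length; must be divisible by
#'   `2^hierarchy_levels`
#' @return a `model_config`
#' @export
model_config <- function(k_out, hierarchy_levels = 2L, base_filters = 16L,
                         L = 0L, z_channels = 8L,
                         variant = c("lean_lc", "deep_lc"), dims = 2L,
                         patch_size = 64L) {
  variant <- match.arg(variant)
  stopifnot(k_out >= 1L, hierarchy_levels >= 2L, base_filters >= 1L,
            z_channels >= 1L, dims %in% c(2L, 3L))
  if (L > hierarchy_levels - 1L)
    stop("model_config: L must be <= hierarchy_levels - 1")
  if (patch_size %% 2L^hierarchy_levels != 0L)
    stop("model_config: patch_size must be divisible by 2^hierarchy_levels")
  structure(list(k_out = as.integer(k_out),
                 hierarchy_levels = as.integer(hierarchy_levels),
                 base_filters = as.integer(base_filters),
                 L = as.integer(L), z_channels = as.integer(z_channels),
                 variant = variant, dims = as.integer(dims),
                 patch_size = as.integer(patch_size)),
            class = "model_config")
}

# spatial side length of hierarchy level i (1-based); level 0 = patch size
.level_size <- function(cfg, i) cfg$patch_size %/% 2L^max(0L, i - cfg$L)

# side length level i would have with no lateral context (KL crop target)
.level_size_no_lc <- function(cfg, i) cfg$patch_size %/% 2L^i

#' Build a model with seeded parameter initialization
#'
#' @param config a [model_config()]
#' @param seed initialization seed; two builds with the same seed have
#'   identical parameters
#' @return a `vse_model`: parameters, config and (initially unset)
#'   normalization statistics
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  C <- config$base_filters; Zc <- config$z_channels
  n <- config$hierarchy_levels; L <- config$L
  deep <- config$variant == "deep_lc"
  params <- list()
  with_seed(seed, {
    conv <- function(name, cin, cout, k = 3L) {
      fan <- k * k * cin
      params[[paste0(name, "_w")]] <<-
        matrix(stats::rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout)
      params[[paste0(name, "_b")]] <<- matrix(0, 1L, cout)
    }
    conv("stem1", 1L, C); conv("stem2", C, C)
    for (i in seq_len(n)) {
      if (i <= L) {
        conv(paste0("br", i, "_1"), 1L, C)
        conv(paste0("br", i, "_2"), C, C)
        if (deep) conv(paste0("br", i, "_3"), C, C)
        conv(paste0("merge", i), 2L * C, C)
        if (deep) conv(paste0("merge", i, "b"), C, C)
      } else {
        conv(paste0("enc", i), C, C)
      }
    }
    conv("q_top", C, 2L * Zc, k = 1L)
    conv(paste0("td", n), Zc, C)
    for (i in seq_len(n - 1L)) {
      conv(paste0("pr", i), C, 2L * Zc, k = 1L)
      conv(paste0("po", i), 2L * C, 2L * Zc, k = 1L)
      conv(paste0("td", i), C + Zc, C)
      if (deep) conv(paste0("td", i, "b"), C, C)
    }
    conv("fin", C, C)
    if (deep) conv("finb", C, C)
    conv("head", C, 2L * config$k_out)
    # start the latent log-variances low so early samples do not drown the
    # signal path in noise (standard ladder-VAE initialization)
    for (nm in grep("^(q_top|pr[0-9]+|po[0-9]+)_b$", names(params),
                    value = TRUE))
      params[[nm]][1L, (Zc + 1L):(2L * Zc)] <- -2
  })
  structure(list(params = params, config = config, norm = NULL),
            class = "vse_model")
}

#' @export
print.vse_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<vse_model>", x$config$variant, "k_out =", x$config$k_out,
      "levels =", x$config$hierarchy_levels, "L =", x$config$L,
      sprintf("(%d parameters)\n", np))
  invisible(x)
}

#' Estimate and attach normalization statistics
#'
#' The mixed input is standardized by its training-set mean/s.d.; each
#' target channel by its own. Statistics travel with the model checkpoint.
#'
#' @param model a `vse_model`
#' @param sampler a patch sampler from [make_patch_sampler()]
#' @param n_patches patches used for the estimate
#' @param seed sampling seed
#' @export
set_normalization <- function(model, sampler, n_patches = 64L, seed = 17L) {
  b <- sampler(n_patches, seed)
  k <- dim(b$targets)[3L]
  t_mean <- numeric(k); t_sd <- numeric(k)
  for (i in seq_len(k)) {
    t_mean[i] <- mean(b$targets[, , i, ])
    t_sd[i] <- max(stats::sd(b$targets[, , i, ]), 1e-8)
  }
  model$norm <- list(in_mean = mean(b$primary),
                     in_sd = max(stats::sd(b$primary), 1e-8),
                     t_mean = t_mean, t_sd = t_sd)
  model
}

.LV_CLAMP <- 8

# ---- forward graph ----------------------------------------------------------

# batch arrays -> constant input nodes (normalized)
.input_nodes <- function(tape, model, batch) {
  nm <- model$norm
  if (is.null(nm)) stop("model has no normalization statistics; call ",
                        "set_normalization() first")
  d <- dim(batch$primary)
  h <- d[1L]; w <- d[2L]; nb <- if (length(d) == 3L) d[3L] else 1L
  if (h != model$config$patch_size)
    stop("batch patch size ", h, " does not match model config ",
         model$config$patch_size)
  prim <- ad_const(tape,
                   matrix((as.vector(batch$primary) - nm$in_mean) / nm$in_sd,
                          ncol = 1L), n = nb, h = h, w = w)
  L <- model$config$L
  if (L > 0L && length(batch$contexts) < L)
    stop("model expects ", L, " context levels, batch has ",
         length(batch$contexts))
  ctxs <- if (L > 0L) lapply(seq_len(L), function(l)
    ad_const(tape,
             matrix((as.vector(batch$contexts[[l]]) - nm$in_mean) / nm$in_sd,
                    ncol = 1L), n = nb, h = h, w = w)) else list()
  list(primary = prim, contexts = ctxs, nb = nb, h = h, w = w)
}

.conv_block <- function(tape, P, x, name) {
  y <- ad_conv2d(tape, x, P[[paste0(name, "_w")]], P[[paste0(name, "_b")]])
  ad_relu(tape, y)
}

.conv1 <- function(tape, P, x, name) {
  ad_conv2d(tape, x, P[[paste0(name, "_w")]], P[[paste0(name, "_b")]],
            kh = 1L, kw = 1L)
}

#' Bottom-up encoding of an input batch
#'
#' Runs the encoder including the lateral-context input branches and
#' returns an encoding object holding the per-level feature maps (and, for
#' context levels, the zero-padded pooled features prior to concatenation,
#' exposed for shape/padding probes).
#'
#' @param model a `vse_model` with normalization set
#' @param batch a batch as produced by a patch sampler, or the result of
#'   [lc_batch()] for a single `lc_patch`
#' @return a `vse_encoding`
#' @export
encode <- function(model, batch) {
  cfg <- model$config
  tape <- ad_tape()
  P <- lapply(model$params, function(v) ad_param(tape, v))
  inp <- .input_nodes(tape, model, batch)
  e0 <- .conv_block(tape, P, inp$primary, "stem1")
  e0 <- .conv_block(tape, P, e0, "stem2")
  feats <- vector("list", cfg$hierarchy_levels)
  padded <- vector("list", cfg$hierarchy_levels)
  prev <- e0
  for (i in seq_len(cfg$hierarchy_levels)) {
    pooled <- ad_avgpool2(tape, prev)
    if (i <= cfg$L) {
      br <- .conv_block(tape, P, inp$contexts[[i]], paste0("br", i, "_1"))
      br <- .conv_block(tape, P, br, paste0("br", i, "_2"))
      if (cfg$variant == "deep_lc")
        br <- .conv_block(tape, P, br, paste0("br", i, "_3"))
      pad <- ad_pad_center(tape, pooled, inp$h, inp$w)
      padded[[i]] <- pad
      m <- ad_concat(tape, pad, br)
      f <- .conv_block(tape, P, m, paste0("merge", i))
      if (cfg$variant == "deep_lc")
        f <- .conv_block(tape, P, f, paste0("merge", i, "b"))
      feats[[i]] <- f
    } else {
      feats[[i]] <- .conv_block(tape, P, pooled, paste0("enc", i))
    }
    prev <- feats[[i]]
  }
  structure(list(tape = tape, pnodes = P, features = feats, padded = padded,
                 input = inp, model = model),
            class = "vse_encoding")
}

# top-down pass on an existing encoding; builds the full stochastic graph.
# mode "sample" draws eps ~ N(0,1) under `seed`; "posterior_mean" uses the
# posterior means; zero_variance forces the sampled z to the posterior mean
# while keeping the variational graph intact.
.decode_graph <- function(enc, mode = c("sample", "posterior_mean"),
                          seed = 1L, zero_variance = FALSE) {
  mode <- match.arg(mode)
  model <- enc$model; cfg <- model$config
  tape <- enc$tape; P <- enc$pnodes
  n <- cfg$hierarchy_levels; Zc <- cfg$z_channels
  eps_for <- function(node) {
    if (mode == "posterior_mean" || zero_variance)
      matrix(0, nrow(node$val), Zc)
    else matrix(stats::rnorm(nrow(node$val) * Zc), ncol = Zc)
  }
  latents <- vector("list", n)
  build_level <- function(feat_node, prior_src, i) {
    if (is.null(prior_src)) {
      q <- .conv1(tape, P, feat_node, "q_top")
      rows <- nrow(feat_node$val)
      mu_p <- ad_const(tape, matrix(0, rows, Zc), n = feat_node$n,
                       h = feat_node$h, w = feat_node$w)
      lv_p <- ad_const(tape, matrix(0, rows, Zc), n = feat_node$n,
                       h = feat_node$h, w = feat_node$w)
    } else {
      pr <- .conv1(tape, P, prior_src, paste0("pr", i))
      mu_p <- ad_slice_cols(tape, pr, 1L, Zc)
      lv_p <- ad_clamp(tape, ad_slice_cols(tape, pr, Zc + 1L, 2L * Zc),
                       -.LV_CLAMP, .LV_CLAMP)
      q <- .conv1(tape, P, ad_concat(tape, enc$features[[i]], prior_src),
                  paste0("po", i))
    }
    mu_q <- ad_slice_cols(tape, q, 1L, Zc)
    lv_q <- ad_clamp(tape, ad_slice_cols(tape, q, Zc + 1L, 2L * Zc),
                     -.LV_CLAMP, .LV_CLAMP)
    z <- if (mode == "posterior_mean" || zero_variance) mu_q
         else ad_sample_gauss(tape, mu_q, lv_q, eps_for(mu_q))
    if (anyNA(z$val))
      stop("decode: NaN in latents at hierarchy level ", i)
    list(mu_q = mu_q, lv_q = lv_q, mu_p = mu_p, lv_p = lv_p, z = z)
  }
  # With lateral context, the level-i feature grid lives in the i-th
  # context window's downscaled coordinates: the primary patch occupies
  # only the central half (the same geometry that motivates the
  # center-cropped KL). Moving top-down into a finer level therefore
  # center-crops the inner half of the state and upsamples it 2x,
  # zooming back toward primary coordinates; without context the grids
  # simply double and a plain upsampling suffices.
  # nearest upsample + fixed smoothing = bilinear interpolation
  up2 <- function(d) ad_blur121(tape, ad_upsample2(tape, d))
  zoom_to <- function(d, g) {
    if (g == 2L * d$h) up2(d)
    else if (g == d$h)
      up2(ad_crop_center(tape, d, d$h %/% 2L, d$w %/% 2L))
    else stop("internal: inconsistent hierarchy geometry")
  }
  with_seed(seed, {
    lt <- build_level(enc$features[[n]], NULL, n)
    latents[[n]] <- lt
    d <- .conv_block(tape, P, lt$z, paste0("td", n))
    if (n > 1L) for (i in seq(n - 1L, 1L)) {
      d <- zoom_to(d, .level_size(cfg, i))
      lt <- build_level(enc$features[[i]], d, i)
      latents[[i]] <- lt
      d <- .conv_block(tape, P, ad_concat(tape, d, lt$z), paste0("td", i))
      if (cfg$variant == "deep_lc")
        d <- .conv_block(tape, P, d, paste0("td", i, "b"))
    }
    d <- zoom_to(d, enc$input$h)
    d <- .conv_block(tape, P, d, "fin")
    if (cfg$variant == "deep_lc") d <- .conv_block(tape, P, d, "finb")
    out <- ad_conv2d(tape, d, P$head_w, P$head_b)
    k <- cfg$k_out
    mu <- ad_slice_cols(tape, out, 1L, k)
    lv <- ad_clamp(tape, ad_slice_cols(tape, out, k + 1L, 2L * k),
                   -.LV_CLAMP, .LV_CLAMP)
    list(pred_mu = mu, pred_lv = lv, latents = latents)
  })
}

#' Decode a prediction from an encoding
#'
#' `mode = "sample"` draws the per-level latents from the inferred
#' posterior (seeded, reproducible); `mode = "posterior_mean"` uses the
#' posterior means and is deterministic. Predictions are returned in raw
#' intensity units (de-normalized per channel).
#'
#' @param model a `vse_model`
#' @param encoding result of [encode()]
#' @param mode `"sample"` or `"posterior_mean"`
#' @param seed RNG seed for the latent draws
#' @param zero_variance force zero posterior variance (samples then equal
#'   the posterior mean)
#' @return list with `pred` (array `(h, w, k, n)`), `pred_logvar`
#'   (normalized scale) and `latents` (per level: posterior/prior mean and
#'   log-variance arrays)
#' @export
decode_sample <- function(model, encoding, mode = c("sample", "posterior_mean"),
                          seed = 1L, zero_variance = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(encoding, "vse_encoding"))
  g <- .decode_graph(encoding, mode, seed, zero_variance)
  nm <- model$norm
  k <- model$config$k_out
  nb <- encoding$input$nb; h <- encoding$input$h; w <- encoding$input$w
  pred <- array(0, c(h, w, k, nb))
  for (c in seq_len(k))
    pred[, , c, ] <- array(g$pred_mu$val[, c] * nm$t_sd[c] + nm$t_mean[c],
                           c(h, w, nb))
  lat <- lapply(g$latents, function(l)
    list(mu_q = l$mu_q$val, lv_q = l$lv_q$val,
         mu_p = l$mu_p$val, lv_p = l$lv_p$val,
         shape = c(l$mu_q$n, l$mu_q$h, l$mu_q$w)))
  list(pred = pred, pred_logvar = g$pred_lv$val, latents = lat)
}

#' Wrap a single `lc_patch` as a one-element batch
#'
#' @param lp an `lc_patch`
#' @export
lc_batch <- function(lp) {
  stopifnot(inherits(lp, "lc_patch"))
  h <- nrow(lp$primary); w <- ncol(lp$primary)
  list(primary = array(lp$primary, c(h, w, 1L)),
       contexts = lapply(lp$contexts, function(m) array(m, c(h, w, 1L))))
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds parameters, configuration, normalization
#' statistics, an optional noise-model reference and a format version;
#' save -> load -> predict is bit-identical.
#'
#' @param model a `vse_model`
#' @param path file path (`.rds`)
#' @param noise_model optional `noise_model` stored alongside
#' @export
save_model <- function(model, path, noise_model = NULL) {
  obj <- list(format_version = 1L, params = model$params,
              config = unclass(model$config), norm = model$norm,
              noise_model = if (!is.null(noise_model)) unclass(noise_model),
              package_version = as.character(utils::packageVersion("vsplit")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  cfg <- structure(obj$config, class = "model_config")
  m <- structure(list(params = obj$params, config = cfg, norm = obj$norm),
                 class = "vse_model")
  nm <- if (!is.null(obj$noise_model))
    structure(obj$noise_model, class = "noise_model")
  attr(m, "noise_model") <- nm
  m
}
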