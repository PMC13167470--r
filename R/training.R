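#' Training configuration
#'
#' Defaults mirror the full-scale protocol: batch size 32, up to 400
#' epochs, learning rate 0.001, the Adamax optimizer, and a
#' reduce-on-plateau learning-rate schedule with patience 150 monitoring
#' the validation loss (reduction factor 0.5, floor 1e-6). One epoch is
#' `steps_per_epoch` freshly sampled batches. Desk-scale runs shrink
#' `max_epoch`, `batch_size` and `steps_per_epoch` rather than changing
#' the protocol.
#'
#' @param batch_size patches per optimization step (>= 1)
#' @param max_epoch epoch budget
#' @param learning_rate initial Adamax step size (> 0)
#' @param lr_patience non-improving epochs before the learning rate is
#'   halved
#' @param lr_factor multiplicative reduction factor
#' @param min_lr learning-rate floor
#' @param steps_per_epoch sampled batches per epoch
#' @param val_batches validation batches per epoch
#' @param seed master training seed
#' @param grad_clip optional gradient-norm clip (`Inf` disables)
#' @param early_stop_patience optional early stop (in epochs; `Inf`
#'   disables)
#' @param kl_warmup_epochs epochs over which the KL weight is annealed
#'   linearly from 0 to its configured value; prevents early posterior
#'   collapse (0 disables)
#' @export
train_config <- function(batch_size = 32L, max_epoch = 400L,
                         learning_rate = 0.001, lr_patience = 150L,
                         lr_factor = 0.5, min_lr = 1e-6,
                         steps_per_epoch = 20L, val_batches = 2L,
                         seed = 1L, grad_clip = Inf,
                         early_stop_patience = Inf,
                         kl_warmup_epochs = 3L) {
  stopifnot(batch_size >= 1L, learning_rate > 0, max_epoch >= 0L,
            lr_patience >= 1L, lr_factor > 0, lr_factor < 1,
            kl_warmup_epochs >= 0L)
  structure(list(batch_size = as.integer(batch_size),
                 max_epoch = as.integer(max_epoch),
                 learning_rate = learning_rate,
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor, min_lr = min_lr,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 val_batches = as.integer(val_batches),
                 seed = as.integer(seed), grad_clip = grad_clip,
                 early_stop_patience = early_stop_patience,
                 kl_warmup_epochs = as.integer(kl_warmup_epochs)),
            class = "train_config")
}

# Adamax update state
.adamax_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       u = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-7)
}

.adamax_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  bc <- 1 - state$beta1^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$u[[nm]] <- pmax(state$beta2 * state$u[[nm]], abs(g))
    params[[nm]] <- params[[nm]] -
      (lr / bc) * state$m[[nm]] / (state$u[[nm]] + state$eps)
  }
  list(state = state, params = params)
}

# reduce-on-plateau bookkeeping: returns updated scheduler state
.plateau_update <- function(sch, val) {
  if (val < sch$best - 1e-12) {
    sch$best <- val; sch$bad <- 0L
  } else {
    sch$bad <- sch$bad + 1L
    if (sch$bad >= sch$patience) {
      sch$lr <- max(sch$lr * sch$factor, sch$min_lr)
      sch$bad <- 0L
    }
  }
  sch
}

# one optimization step: returns list(params updated elsewhere, grads, terms)
.train_step <- function(model, batch, noise_model, loss_cfg, step_seed,
                        nz = 1L, kl_scale = 1) {
  enc <- encode(model, batch)
  dec <- .decode_graph(enc, mode = "sample", seed = step_seed)
  lg <- .loss_graph(model, enc, dec, batch, noise_model, loss_cfg, nz = nz,
                    kl_scale = kl_scale)
  ad_backward(enc$tape, lg$loss)
  grads <- lapply(enc$pnodes, function(nd) nd$grad)
  list(loss = lg$loss$val[1L], terms = lg$terms, grads = grads)
}

#' Train a splitting encoder-decoder
#'
#' Full, seeded optimization loop: per epoch, `steps_per_epoch` freshly
#' sampled batches are stepped with Adamax; validation loss (sampled from
#' `val_sampler` with a disjoint seed stream) drives the
#' reduce-on-plateau schedule and best-checkpoint retention. A non-finite
#' loss aborts with a diagnostic naming the offending term.
#'
#' @param model a `vse_model` (normalization set automatically from the
#'   training sampler if missing)
#' @param train_sampler,val_sampler patch samplers from
#'   [make_patch_sampler()]
#' @param loss_cfg a [loss_config()]
#' @param train_cfg a [train_config()]
#' @param noise_model `noise_model` for the denoising branch (required
#'   when `loss_cfg$w > 0`)
#' @param nz z-slices folded into the batch axis (volumetric training)
#' @param verbose print per-epoch progress
#' @return list with `model` (best-validation parameters), `history`
#'   (data.frame: epoch, train/val loss, term breakdown, lr)
#' @export
train <- function(model, train_sampler, val_sampler = NULL,
                  loss_cfg = loss_config(), train_cfg = train_config(),
                  noise_model = NULL, nz = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "vse_model"), inherits(train_cfg, "train_config"))
  if (is.null(model$norm))
    model <- set_normalization(model, train_sampler,
                               seed = derive_seed(train_cfg$seed, "norm"))
  if (is.null(val_sampler)) val_sampler <- train_sampler
  history <- list()
  if (train_cfg$max_epoch == 0L)
    return(list(model = model, history = data.frame()))
  opt <- .adamax_init(model$params)
  sch <- list(lr = train_cfg$learning_rate, factor = train_cfg$lr_factor,
              patience = train_cfg$lr_patience, min_lr = train_cfg$min_lr,
              best = Inf, bad = 0L)
  best_val <- Inf; best_params <- model$params; no_improve <- 0L
  for (epoch in seq_len(train_cfg$max_epoch)) {
    kl_scale <- if (train_cfg$kl_warmup_epochs > 0L)
      min(1, epoch / train_cfg$kl_warmup_epochs) else 1
    tr_losses <- numeric(train_cfg$steps_per_epoch)
    terms_acc <- NULL
    for (s in seq_len(train_cfg$steps_per_epoch)) {
      bseed <- derive_seed(train_cfg$seed, sprintf("e%d_s%d", epoch, s))
      batch <- train_sampler(train_cfg$batch_size, bseed)
      st <- .train_step(model, batch, noise_model, loss_cfg,
                        step_seed = derive_seed(bseed, "z"), nz = nz,
                        kl_scale = kl_scale)
      if (!is.finite(st$loss))
        stop("train: non-finite loss at epoch ", epoch, " step ", s)
      if (is.finite(train_cfg$grad_clip)) {
        gn <- sqrt(sum(vapply(st$grads, function(g)
          if (is.null(g)) 0 else sum(g * g), 0)))
        if (gn > train_cfg$grad_clip)
          st$grads <- lapply(st$grads, function(g)
            if (is.null(g)) g else g * (train_cfg$grad_clip / gn))
      }
      up <- .adamax_step(opt, model$params, st$grads, sch$lr)
      opt <- up$state; model$params <- up$params
      tr_losses[s] <- st$loss
      terms_acc <- if (is.null(terms_acc)) st$terms else terms_acc
    }
    vrec <- validate(model, val_sampler, loss_cfg, train_cfg,
                     noise_model = noise_model, epoch = epoch, nz = nz)
    sch <- .plateau_update(sch, vrec$loss)
    if (vrec$loss < best_val) {
      best_val <- vrec$loss; best_params <- model$params; no_improve <- 0L
    } else no_improve <- no_improve + 1L
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = mean(tr_losses), val_loss = vrec$loss,
      kl = terms_acc$kl,
      nll_denoise = terms_acc$nll_denoise %||% NA_real_,
      nll_direct = terms_acc$nll_direct %||% NA_real_,
      lr = sch$lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, mean(tr_losses), vrec$loss, sch$lr))
    if (no_improve >= train_cfg$early_stop_patience) break
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, history))
}

#' Evaluate loss (and optional metrics) on held-out batches
#'
#' Deterministic under a fixed configuration: validation batches come from
#' a seed stream disjoint from training, and decoding uses posterior
#' means.
#'
#' @param model a `vse_model`
#' @param val_sampler a patch sampler
#' @param loss_cfg,train_cfg configurations
#' @param noise_model noise model for the denoising branch
#' @param metrics optional character vector of extra per-batch metrics to
#'   record (`"psnr"` supported); empty gives a loss-only record
#' @param epoch epoch tag used to derive the validation seeds
#' @param nz z-slices folded into the batch axis
#' @return list with `loss` and optional metric entries
#' @export
validate <- function(model, val_sampler, loss_cfg = loss_config(),
                     train_cfg = train_config(), noise_model = NULL,
                     metrics = character(), epoch = 0L, nz = 1L) {
  nb <- train_cfg$val_batches
  if (nb < 1L) stop("validate: empty validation set")
  losses <- numeric(nb)
  psnrs <- c()
  for (i in seq_len(nb)) {
    vseed <- derive_seed(train_cfg$seed, sprintf("val%d_%d", epoch, i))
    batch <- val_sampler(train_cfg$batch_size, vseed)
    enc <- encode(model, batch)
    dec <- .decode_graph(enc, mode = "posterior_mean")
    lg <- .loss_graph(model, enc, dec, batch, noise_model, loss_cfg, nz = nz)
    losses[i] <- lg$loss$val[1L]
    if ("psnr" %in% metrics && !is.null(batch$clean)) {
      pr <- decode_sample(model, enc, mode = "posterior_mean")
      psnrs <- c(psnrs, care_psnr(pr$pred, batch$clean))
    }
  }
  out <- list(loss = mean(losses))
  if (length(psnrs)) out$psnr <- mean(psnrs)
  out
}
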