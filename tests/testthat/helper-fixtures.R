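# shared fixtures and independent oracles

# small two-channel phantom stack (bars vs spots) reused across tests
test_stack <- function(h = 128L, w = 128L, seed = 1L, spot_amp = c(80, 120)) {
  bars <- generate_structure_channel("filaments", c(h, w), 5e-4,
                                     seed = seed)
  spots <- generate_structure_channel("puncta", c(h, w), 2e-3,
                                      seed = seed + 1L, size_scale = 2,
                                      amp_range = spot_amp)
  dat <- array(0, c(2L, h, w))
  dat[1L, , ] <- stack_channel(bars, 1L)
  dat[2L, , ] <- stack_channel(spots, 1L)
  channel_stack(dat, channel_names = c("bars", "spots"))
}

# independent connected-component counter (4-connectivity, BFS over a
# binary mask); oracle for object counts in generated phantoms
count_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1L)
    lab[i, j] <- cur
    while (nrow(queue) > 0L) {
      p <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        y <- p[1L] + d[1L]; x <- p[2L] + d[2L]
        if (y >= 1L && y <= h && x >= 1L && x <= w &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          queue <- rbind(queue, c(y, x))
        }
      }
    }
  }
  cur
}

# tiny trained-free model with normalization attached, for inference and
# shape tests that do not need a useful fit
tiny_model <- function(L = 1L, levels = 2L, patch = 32L, k = 2L,
                       variant = "lean_lc", seed = 1L) {
  cfg <- model_config(k_out = k, hierarchy_levels = levels,
                      base_filters = 8L, L = L, z_channels = 4L,
                      variant = variant, patch_size = patch)
  m <- build_model(cfg, seed = seed)
  stack <- test_stack(96L, 96L, seed = 3L)
  task <- mix_task(2L, mode = "I", noise = noise_spec(10, 2))
  sampler <- make_patch_sampler(stack, task, patch, L = L, frame_seed = 7L)
  set_normalization(m, sampler, n_patches = 8L)
}

# deterministic stand-in predictor for tiling tests: channel 1 doubles the
# primary patch, channel 2 negates it; "samples" are exact copies
stub_model <- function(tile = 64L) {
  structure(list(config = list(k_out = 2L, L = 0L)), class = "stub_model")
}

predict_tile.stub_model <- function(model, lp, S, seed) {
  h <- nrow(lp$primary); w <- ncol(lp$primary)
  out <- array(0, c(h, w, 2L, S))
  for (s in seq_len(S)) {
    out[, , 1L, s] <- 2 * lp$primary
    out[, , 2L, s] <- -lp$primary
  }
  out
}
registerS3method("predict_tile", "stub_model", predict_tile.stub_model)
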