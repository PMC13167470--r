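test_that("config validation enforces the architecture invariants", {
  expect_error(model_config(2, hierarchy_levels = 3, L = 3), "L must be")
  expect_error(model_config(2, hierarchy_levels = 3, patch_size = 36),
               "divisible")
  cfg <- model_config(2, 2, 16, L = 1, patch_size = 64)
  expect_s3_class(cfg, "model_config")
})

test_that("builds are deterministic and parameter counts are fixed per config", {
  cfg <- model_config(2, 2, 8, L = 1, z_channels = 4, patch_size = 32)
  m1 <- build_model(cfg, seed = 5)
  m2 <- build_model(cfg, seed = 5)
  m3 <- build_model(cfg, seed = 6)
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params, m3$params))
  expect_identical(vapply(m1$params, length, 0L),
                   vapply(m3$params, length, 0L))
  # deep variant has strictly more parameters
  deep <- build_model(model_config(2, 2, 8, L = 1, z_channels = 4,
                                   variant = "deep_lc", patch_size = 32), 1)
  expect_gt(sum(vapply(deep$params, length, 0L)),
            sum(vapply(m1$params, length, 0L)))
})

test_that("L = 0: features halve per level, no padding occurs", {
  m <- tiny_model(L = 0, levels = 2, patch = 32)
  st <- test_stack(96, 96, seed = 1)
  task <- mix_task(2, mode = "I", noise = noise_spec(5, 1))
  b <- make_patch_sampler(st, task, 32, L = 0, frame_seed = 1)(2, 1)
  enc <- encode(m, b)
  expect_equal(sapply(enc$features, function(f) f$h), c(16, 8))
  expect_true(all(vapply(enc$padded, is.null, TRUE)))
})

test_that("with LC active every level keeps primary spatial dims and padding borders are zero", {
  m <- tiny_model(L = 2, levels = 3, patch = 32)
  st <- test_stack(96, 96, seed = 2)
  task <- mix_task(2, mode = "I", noise = noise_spec(5, 1))
  b <- make_patch_sampler(st, task, 32, L = 2, frame_seed = 1)(2, 1)
  enc <- encode(m, b)
  expect_equal(sapply(enc$features, function(f) f$h), c(32, 32, 16))
  for (l in 1:2) {
    pad <- enc$padded[[l]]
    v <- array(pad$val[, 1], c(32, 32, 2))
    inner <- 32 / 2  # pooled map occupies the central half
    lead <- (32 - inner) / 2
    expect_true(all(v[1:lead, , ] == 0))
    expect_true(all(v[, 1:lead, ] == 0))
    expect_true(all(v[(32 - lead + 1):32, , ] == 0))
    expect_gt(sum(v[(lead + 1):(32 - lead), (lead + 1):(32 - lead), ] != 0),
              0)
  }
  # input branches maintain primary dims by construction (no pooling):
  # merged features carry them (checked above); prediction does too
  dec <- decode_sample(m, enc, "posterior_mean")
  expect_identical(dim(dec$pred), c(32L, 32L, 2L, 2L))
})

test_that("decode contracts: determinism, seeding, zero-variance degenerate", {
  m <- tiny_model(L = 1, levels = 2, patch = 32)
  st <- test_stack(96, 96, seed = 3)
  task <- mix_task(2, mode = "I", noise = noise_spec(5, 1))
  b <- make_patch_sampler(st, task, 32, L = 1, frame_seed = 1)(2, 1)
  enc <- encode(m, b)
  pm1 <- decode_sample(m, enc, "posterior_mean")
  pm2 <- decode_sample(m, enc, "posterior_mean")
  expect_identical(pm1$pred, pm2$pred)
  s1 <- decode_sample(m, enc, "sample", seed = 4)
  s2 <- decode_sample(m, enc, "sample", seed = 4)
  s3 <- decode_sample(m, enc, "sample", seed = 5)
  expect_identical(s1$pred, s2$pred)
  expect_false(identical(s1$pred, s3$pred))
  z0 <- decode_sample(m, enc, "sample", seed = 6, zero_variance = TRUE)
  expect_equal(z0$pred, pm1$pred, tolerance = 1e-12)
  # latents expose posterior and prior parameters per level
  expect_length(pm1$latents, 2)
  expect_true(all(is.finite(pm1$latents[[1]]$lv_q)))
})

test_that("batch/config mismatches error clearly", {
  m <- tiny_model(L = 1, levels = 2, patch = 32)
  st <- test_stack(96, 96, seed = 4)
  task <- mix_task(2, mode = "I", noise = noise_spec(5, 1))
  b0 <- make_patch_sampler(st, task, 32, L = 0, frame_seed = 1)(1, 1)
  expect_error(encode(m, b0), "context levels")
  b64 <- make_patch_sampler(st, task, 64, L = 1, frame_seed = 1)(1, 1)
  expect_error(encode(m, b64), "patch size")
  m_nonorm <- build_model(model_config(2, 2, 8, L = 0, patch_size = 32), 1)
  b1 <- make_patch_sampler(st, task, 32, L = 0, frame_seed = 1)(1, 1)
  expect_error(encode(m_nonorm, b1), "normalization")
})

test_that("checkpoint save/load round-trip is bit-identical", {
  m <- tiny_model(L = 1, levels = 2, patch = 32)
  st <- test_stack(96, 96, seed = 5)
  task <- mix_task(2, mode = "I", noise = noise_spec(5, 1))
  b <- make_patch_sampler(st, task, 32, L = 1, frame_seed = 1)(1, 1)
  before <- decode_sample(m, encode(m, b), "sample", seed = 3)$pred
  path <- tempfile(fileext = ".rds")
  save_model(m, path, noise_model = pg_noise_model(1, 5))
  m2 <- load_model(path)
  after <- decode_sample(m2, encode(m2, b), "sample", seed = 3)$pred
  expect_identical(before, after)
  expect_equal(attr(m2, "noise_model")$kind, "pg")
})
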