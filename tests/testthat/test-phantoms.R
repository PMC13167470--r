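test_that("structure generator: empty case, determinism, unknown kind", {
  z <- generate_structure_channel("puncta", c(128, 128), density = 0,
                                  seed = 1)
  expect_true(all(stack_channel(z, 1) == 0))
  a <- generate_structure_channel("rings", c(64, 64), 5e-4, seed = 9)
  b <- generate_structure_channel("rings", c(64, 64), 5e-4, seed = 9)
  expect_identical(a$data, b$data)
  expect_error(generate_structure_channel("squiggles", c(64, 64), 1e-3),
               "unknown kind")
  expect_error(generate_structure_channel("puncta", c(16, 16), 1e-3))
})

test_that("puncta count matches the connected-component oracle", {
  d <- 8e-4  # sparse enough that spots rarely merge
  counts <- vapply(1:6, function(s) {
    img <- stack_channel(generate_structure_channel("puncta", c(256, 256),
                                                    d, seed = 100 + s), 1)
    count_components(img > 1)
  }, 0L)
  lambda <- d * 256 * 256  # expected objects per frame
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 6) + 2)
})

test_that("every kind renders finite non-negative foreground on zero background", {
  for (kind in c("filaments", "blobs", "puncta", "rings")) {
    img <- stack_channel(generate_structure_channel(kind, c(96, 96), 1e-3,
                                                    seed = 4), 1)
    expect_true(all(is.finite(img)))
    expect_true(all(img >= 0))
    expect_gt(max(img), 10)            # some foreground
    expect_gt(mean(img == 0), 0.01)    # exact-zero background exists
  }
})

test_that("mix_channels matches element-wise arithmetic and validates weights", {
  st <- test_stack(64, 64, seed = 2)
  expect_equal(mix_channels(st, c(1, 1)),
               stack_channel(st, 1) + stack_channel(st, 2))
  expect_equal(mix_channels(st, c(2, 1)),
               2 * stack_channel(st, 1) + stack_channel(st, 2))
  one <- channel_stack(array(stack_channel(st, 1), c(1, 64, 64)))
  expect_equal(mix_channels(one, 1), stack_channel(st, 1))
  expect_error(mix_channels(st, c(1, 1, 1)), "weights")
})

test_that("mode I: input equals weighted target sum and preserves correlation", {
  st <- generate_colocalized_channels(c(128, 128), rho = 0.6, seed = 5)
  pr <- assemble_mode_I(st, c(10, 20), 64)
  expect_identical(pr$input, pr$targets[1, , ] + pr$targets[2, , ])
  expect_equal(max(abs(pr$input - pr$targets[1, , ] - pr$targets[2, , ])), 0)
  # correlation between target channels matches the source stack
  r_src <- cor(as.vector(stack_channel(st, 1)),
               as.vector(stack_channel(st, 2)))
  r_pair <- cor(as.vector(pr$targets[1, , ]), as.vector(pr$targets[2, , ]))
  expect_gt(r_src, 0.5)
  expect_lt(abs(r_src - r_pair), 0.15)
  pw <- assemble_mode_I(st, c(1, 1), 32, weights = c(2, 1))
  expect_equal(pw$input, 2 * pw$targets[1, , ] + pw$targets[2, , ])
})

test_that("mode II destroys cross-channel correlation; degenerate case = mode I", {
  st <- generate_colocalized_channels(c(200, 200), rho = 0.6, seed = 6)
  s1 <- channel_stack(array(stack_channel(st, 1), c(1, 200, 200)))
  s2 <- channel_stack(array(stack_channel(st, 2), c(1, 200, 200)))
  # pooled correlation over many independent draws, >> 10,000 pixels
  draws <- lapply(1:50, function(i) assemble_mode_II(list(s1, s2), 48,
                                                     seed = i))
  t1 <- unlist(lapply(draws, function(d) as.vector(d$targets[1, , ])))
  t2 <- unlist(lapply(draws, function(d) as.vector(d$targets[2, , ])))
  expect_lt(abs(cor(t1, t2)), 0.05)
  # while mode-I pairs from the same phantom stay strongly correlated
  m1_draws <- lapply(seq(1, 100, by = 11), function(o)
    assemble_mode_I(st, c(o, o), 48))
  u1 <- unlist(lapply(m1_draws, function(d) as.vector(d$targets[1, , ])))
  u2 <- unlist(lapply(m1_draws, function(d) as.vector(d$targets[2, , ])))
  expect_gt(cor(u1, u2), 0.4)
  # forcing one location per channel reduces to mode I on that pairing
  pr <- assemble_mode_II(list(s1, s2), 48, seed = 1,
                         origins = list(c(5, 9), c(5, 9)))
  m1 <- assemble_mode_I(st, c(5, 9), 48)
  expect_equal(pr$targets, m1$targets)
  # fixed seed -> reproducible pairing sequence
  a <- assemble_mode_II(list(s1, s2), 48, seed = 42)
  b <- assemble_mode_II(list(s1, s2), 48, seed = 42)
  expect_identical(a$origins, b$origins)
  expect_error(assemble_mode_II(list(s1), 48, k = 2), "at least")
})

test_that("mode IIb: exact pair sum, uniform pairing, paper-scale crop lists", {
  set.seed(8)
  a <- list(matrix(runif(100 * 100, 0, 50), 100))
  b <- list(matrix(runif(100 * 100, 0, 50), 100))
  pr <- assemble_mode_IIb(a, b, 100, seed = 1)
  expect_equal(pr$input, a[[1]] + b[[1]])
  expect_error(assemble_mode_IIb(list(), b, 64), "empty crop list")
  # pairing approximately uniform over crop pairs (frequency oracle)
  crops_a <- lapply(1:4, function(i) matrix(i, 32, 32))
  crops_b <- lapply(1:3, function(i) matrix(10 * i, 32, 32))
  pairs <- t(vapply(1:600, function(s)
    assemble_mode_IIb(crops_a, crops_b, 32, seed = s)$pair, c(0L, 0L)))
  tab <- table(factor(pairs[, 1], 1:4), factor(pairs[, 2], 1:3))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  # the reference collection scale (82 + 48 regions) is representable
  many_a <- rep(list(matrix(1, 100, 100)), 82)
  many_b <- rep(list(matrix(2, 100, 100)), 48)
  pr2 <- assemble_mode_IIb(many_a, many_b, 100, seed = 3)
  expect_equal(unique(as.vector(pr2$input)), 3)
})

test_that("mode III: acquired input is independent of target noise", {
  st <- test_stack(96, 96, seed = 10)
  spec <- noise_spec(8, 0)
  n1 <- apply_noise(stack_channel(st, 1), noise_spec(8, 0, seed = 1))
  n2 <- apply_noise(stack_channel(st, 2), noise_spec(8, 0, seed = 2))
  clean_sum <- stack_channel(st, 1) + stack_channel(st, 2)
  # average many fresh acquisitions of the superimposed channel
  acq <- Reduce(`+`, lapply(1:80, function(s)
    apply_noise(clean_sum, noise_spec(8, 0, seed = 100 + s)))) / 80
  expect_lt(max(abs(acq - clean_sum)), 8)  # sigma/sqrt(80) * ~8 sd margin
  dat <- array(0, c(3, 96, 96))
  dat[1, , ] <- n1; dat[2, , ] <- n2
  dat[3, , ] <- apply_noise(clean_sum, noise_spec(8, 0, seed = 99))
  st3 <- channel_stack(dat, is_noisy = TRUE)
  pr <- assemble_mode_III(st3, c(1, 1), 48)
  expect_false(isTRUE(all.equal(pr$input,
                                pr$targets[1, , ] + pr$targets[2, , ])))
  # zero noise: mode III degenerates to mode I
  dat0 <- array(0, c(3, 96, 96))
  dat0[1, , ] <- stack_channel(st, 1); dat0[2, , ] <- stack_channel(st, 2)
  dat0[3, , ] <- clean_sum
  pr0 <- assemble_mode_III(channel_stack(dat0), c(3, 5), 32)
  m1 <- assemble_mode_I(st, c(3, 5), 32)
  expect_equal(pr0$input, m1$input)
  expect_error(assemble_mode_III(st, c(1, 1), 32), "superimposed")
})

test_that("scaled-copy task: validation, intensity ratio, supported factors", {
  src <- stack_channel(test_stack(192, 192, seed = 12), 1)
  expect_error(make_scaled_copy_task(src, 0.9, 48), ">= 1")
  s1 <- make_scaled_copy_task(src, 1, 48, seed = 3)
  expect_equal(attr(s1, "similarity_scale"), 1)
  # s = 2: mean intensity ratio over many patches approaches 2
  m1 <- 0; m2 <- 0
  for (s in 1:300) {
    tk <- make_scaled_copy_task(src, 2, 32, seed = s)
    m1 <- m1 + mean(stack_channel(tk, 1)); m2 <- m2 + mean(stack_channel(tk, 2))
  }
  expect_lt(abs(m2 / m1 - 2), 0.3)
  for (f in c(1.032, 1.063, 1.125, 1.25, 1.5, 2))
    expect_s3_class(make_scaled_copy_task(src, f, 32, seed = 1),
                    "channel_stack")
})

test_that("apply_noise: identity, Gaussian and Poisson moment oracles", {
  img <- matrix(50, 80, 80)
  expect_identical(apply_noise(img, noise_spec(0, 0)), img)
  # reference read-noise level sigma = 500
  n <- apply_noise(matrix(10000, 200, 200), noise_spec(500, 0, seed = 2))
  s <- sd(n)
  expect_lt(abs(s - 500), 3 * 500 / sqrt(2 * 200 * 200))
  # pure shot noise: variance = value * scale
  v <- 40; sc <- 3
  p <- apply_noise(matrix(v, 200, 200), noise_spec(0, sc, seed = 3))
  expect_lt(abs(var(as.vector(p)) - v * sc), 6 * v * sc / sqrt(200 * 200 / 2))
  expect_error(noise_spec(-1, 0), "gaussian_sigma")
  expect_error(apply_noise(matrix(-5, 4, 4), noise_spec(0, 2)), "negative")
})

test_that("mix_task validates its invariants", {
  expect_error(mix_task(5), "k")
  expect_error(mix_task(2, weights = c(1, 2, 3)))
  expect_error(mix_task(3, mode = "I", similarity_scale = 2), "k = 2")
  expect_error(mix_task(2, similarity_scale = 0.5), ">= 1")
  t <- mix_task(2, c(2, 1), "III", noise_spec(5, 1))
  expect_s3_class(t, "mix_task")
})
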