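rand_latents <- function(seed, C = 3, H = 8, W = 8, levels = 2) {
  set.seed(seed)
  lapply(seq_len(levels), function(i) {
    h <- H / 2^(i - 1)
    list(mu_q = array(rnorm(C * h * h), c(C, h, h)),
         lv_q = array(rnorm(C * h * h, 0, 0.5), c(C, h, h)),
         mu_p = array(rnorm(C * h * h), c(C, h, h)),
         lv_p = array(rnorm(C * h * h, 0, 0.5), c(C, h, h)),
         no_lc_shape = c(h / 2, h / 2))
  })
}

test_that("pixel-wise KL: closed forms and Monte-Carlo oracle", {
  same <- list(list(mu_q = array(1, c(2, 4, 4)), lv_q = array(0.3, c(2, 4, 4)),
                    mu_p = array(1, c(2, 4, 4)), lv_p = array(0.3, c(2, 4, 4))))
  expect_equal(kl_per_level(same)[[1]], array(0, c(2, 4, 4)))
  shift <- list(list(mu_q = array(1, c(1, 2, 2)), lv_q = array(0, c(1, 2, 2)),
                     mu_p = array(0, c(1, 2, 2)), lv_p = array(0, c(1, 2, 2))))
  expect_equal(kl_per_level(shift)[[1]], array(0.5, c(1, 2, 2)),
               tolerance = 1e-12)
  # Monte-Carlo: KL = E_q[log q - log p] at 1e5 draws
  set.seed(1)
  mu_q <- 0.7; lv_q <- -0.4; mu_p <- -0.2; lv_p <- 0.5
  z <- rnorm(1e5, mu_q, exp(lv_q / 2))
  mc <- mean(dnorm(z, mu_q, exp(lv_q / 2), log = TRUE) -
             dnorm(z, mu_p, exp(lv_p / 2), log = TRUE))
  one <- list(list(mu_q = array(mu_q, c(1, 1, 1)),
                   lv_q = array(lv_q, c(1, 1, 1)),
                   mu_p = array(mu_p, c(1, 1, 1)),
                   lv_p = array(lv_p, c(1, 1, 1))))
  kl <- kl_per_level(one)[[1]][1]
  expect_lt(abs(kl - mc), 3 * sd(dnorm(z, mu_q, exp(lv_q / 2), log = TRUE) -
                                 dnorm(z, mu_p, exp(lv_p / 2),
                                       log = TRUE)) / sqrt(1e5))
  bad <- list(list(mu_q = array(0, c(1, 2, 2)), lv_q = array(0, c(1, 2, 2)),
                   mu_p = array(0, c(1, 3, 3)), lv_p = array(0, c(1, 3, 3))))
  expect_error(kl_per_level(bad), "mismatch")
})

test_that("cropped KL: identity crop, enumeration oracle, alpha linearity", {
  set.seed(2)
  KL <- array(abs(rnorm(3 * 8 * 8)), c(3, 8, 8))
  # identity crop: bit-identical to the plain sum
  expect_identical(kl_loss_cropped(KL, c(8, 8), alpha = 1), sum(KL))
  # index-enumeration oracle for a 4x4 center crop (and odd crop parity)
  acc <- 0
  for (j in 1:3) for (h in 3:6) for (w in 3:6) acc <- acc + KL[j, h, w]
  expect_equal(kl_loss_cropped(KL, c(4, 4), alpha = 1), acc,
               tolerance = 1e-12)
  acc3 <- 0  # 3x3 crop of 8: offset floor(5/2)=2, rows 3:5 (extra trailing
  for (j in 1:3) for (h in 3:5) for (w in 3:5) acc3 <- acc3 + KL[j, h, w]
  expect_equal(kl_loss_cropped(KL, c(3, 3), alpha = 1), acc3)
  expect_equal(kl_loss_cropped(KL, c(4, 4), alpha = 2),
               2 * kl_loss_cropped(KL, c(4, 4), alpha = 1))
  expect_error(kl_loss_cropped(KL, c(10, 10)), "larger")
})

test_that("volumetric KL: z-averaging makes the scalar replication-invariant", {
  set.seed(3)
  base <- array(abs(rnorm(2 * 6 * 6)), c(2, 6, 6))
  vals <- vapply(c(1, 4, 16), function(Z) {
    KL4 <- array(0, c(2, Z, 6, 6))
    for (z in seq_len(Z)) KL4[, z, , ] <- base
    kl_loss_3d(KL4, c(4, 4), alpha = 1)
  }, 0)
  expect_equal(vals[1], vals[2], tolerance = 1e-12)
  expect_equal(vals[2], vals[3], tolerance = 1e-12)
  expect_equal(vals[1], kl_loss_cropped(base, c(4, 4), 1), tolerance = 1e-12)
  # random 4D tensor against the brute-force mean-then-crop-then-sum oracle
  KL4 <- array(abs(rnorm(2 * 3 * 6 * 6)), c(2, 3, 6, 6))
  brute <- 0
  for (j in 1:2) for (h in 2:5) for (w in 2:5)
    brute <- brute + mean(KL4[j, , h, w])
  expect_equal(kl_loss_3d(KL4, c(4, 4), alpha = 1), brute,
               tolerance = 1e-12)
})

test_that("direct likelihood: closed form, quadratic scaling, variance recovery", {
  p <- array(rnorm(32), c(2, 4, 4))
  expect_equal(musplit_likelihood(p, p, sigma = 1),
               0.5 * log(2 * pi) * 32, tolerance = 1e-12)
  t1 <- p + 0.1
  base <- musplit_likelihood(p, t1, sigma = 1) -
    musplit_likelihood(p, p, sigma = 1)
  quad <- musplit_likelihood(p, p + 0.2, sigma = 1) -
    musplit_likelihood(p, p, sigma = 1)
  expect_equal(quad / base, 4, tolerance = 1e-9)
  expect_error(musplit_likelihood(p * NA, t1), "non-finite")
  # the learned-variance likelihood recovers generative heteroscedasticity:
  # closed-form argmin over lv per group equals log(mean residual^2)
  set.seed(4)
  gen_sd <- rep(c(0.5, 1, 2, 4), each = 2500)
  r <- rnorm(1e4, 0, gen_sd)
  lv_hat <- vapply(split(r, rep(1:4, each = 2500)),
                   function(v) log(mean(v^2)), 0)
  expect_gt(cor(lv_hat, log(c(0.5, 1, 2, 4)^2)), 0.9)
  # and the NLL at the recovered variance is below any constant-variance fit
  nll_het <- sum(0.5 * (log(2 * pi) + rep(lv_hat, each = 2500) +
                        r^2 / exp(rep(lv_hat, each = 2500))))
  nll_fixed <- musplit_likelihood(rep(0, 1e4), r, sigma = sd(r))
  expect_lt(nll_het, nll_fixed)
})

test_that("noise-model likelihood: Gaussian equivalence, argmin, tail behavior", {
  set.seed(5)
  pred <- array(runif(64, 20, 80), c(1, 8, 8))
  tgt <- pred + array(rnorm(64, 0, 6), c(1, 8, 8))
  gm <- gaussian_noise_model(6)
  # equals the direct likelihood with fixed sigma, exactly
  expect_equal(denoisplit_likelihood(pred, tgt, gm),
               musplit_likelihood(pred, tgt, sigma = 6), tolerance = 1e-9)
  expect_error(denoisplit_likelihood(pred, tgt, NULL), "missing")
  # analytic argmin over a constant prediction = mean of targets
  grid <- seq(min(tgt), max(tgt), length.out = 400)
  nlls <- vapply(grid, function(c0)
    denoisplit_likelihood(array(c0, dim(tgt)), tgt, gm), 0)
  expect_lt(abs(grid[which.min(nlls)] - mean(tgt)),
            diff(grid[1:2]) * 1.5)
  # heavier-tailed two-component model penalizes outliers less
  s <- runif(5e4, 0, 100)
  o <- s + ifelse(runif(5e4) < 0.2, rnorm(5e4, 0, 30), rnorm(5e4, 0, 5))
  mix <- fit_noise_model(s, o, n_components = 2, seed = 1)
  gau <- gaussian_noise_model(sd(o - s))
  out_pen_mix <- -noise_loglikelihood(mix, 150, 50) +
    noise_loglikelihood(mix, 50, 50)
  out_pen_gau <- -noise_loglikelihood(gau, 150, 50) +
    noise_loglikelihood(gau, 50, 50)
  expect_lt(out_pen_mix, out_pen_gau)
})

test_that("combined objective: branch switches, default w, affinity in w", {
  set.seed(6)
  pred <- array(runif(2 * 8 * 8, 10, 90), c(2, 8, 8))
  tgt <- pred + array(rnorm(2 * 8 * 8, 0, 5), c(2, 8, 8))
  lat <- rand_latents(7)
  nm <- pg_noise_model(1, 5)
  pure_d <- microsplit_loss(pred, tgt, lat, nm, loss_config(w = 1))
  pure_m <- microsplit_loss(pred, tgt, lat, nm,
                            loss_config(w = 0,
                                        likelihood_variance_mode = "fixed"))
  expect_equal(pure_d$loss,
               denoisplit_likelihood(pred, tgt, nm) + pure_d$terms$kl)
  expect_equal(pure_m$loss,
               musplit_likelihood(pred, tgt, sigma = 1) + pure_m$terms$kl)
  expect_equal(loss_config()$w, 0.9)
  # affine in w (exact): fit a line through w = 0, 0.25 and predict 0.5, 1
  ws <- c(0, 0.25, 0.5, 1)
  ls <- vapply(ws, function(w)
    microsplit_loss(pred, tgt, lat, nm,
                    loss_config(w = w,
                                likelihood_variance_mode = "fixed"))$loss, 0)
  slope <- (ls[2] - ls[1]) / 0.25
  expect_equal(ls[3], ls[1] + slope * 0.5, tolerance = 1e-9 * abs(ls[3]))
  expect_equal(ls[4], ls[1] + slope * 1.0, tolerance = 1e-9 * abs(ls[4]))
})

test_that("volumetric graph: z-replicated slices keep the KL invariant and outputs per-slice", {
  st <- test_stack(96, 96, seed = 9)
  task <- mix_task(2, mode = "I", noise = noise_spec(8, 2))
  smp <- make_patch_sampler(st, task, 32, L = 1, frame_seed = 3)
  m <- tiny_model(L = 1, levels = 2, patch = 32, seed = 2)
  b1 <- smp(1, 5)
  # replicate the single slice along z (z folded into the batch axis)
  b4 <- list(primary = array(rep(b1$primary, 4), c(32, 32, 4)),
             contexts = lapply(b1$contexts, function(a)
               array(rep(a, 4), c(32, 32, 4))),
             targets = array(0, c(32, 32, 2, 4)),
             clean = NULL)
  for (z in 1:4) b4$targets[, , , z] <- b1$targets[, , , 1]
  nm <- pg_noise_model(2, 8)
  enc1 <- encode(m, b1)
  dec1 <- vsplit:::.decode_graph(enc1, "posterior_mean")
  lg1 <- vsplit:::.loss_graph(m, enc1, dec1, b1, nm, loss_config(), nz = 1)
  enc4 <- encode(m, b4)
  dec4 <- vsplit:::.decode_graph(enc4, "posterior_mean")
  lg4 <- vsplit:::.loss_graph(m, enc4, dec4, b4, nm, loss_config(), nz = 4)
  # per-slice outputs identical to the single-slice forward (3D parity)
  for (z in 1:4)
    expect_equal(dec4$pred_mu$val[((z - 1) * 1024 + 1):(z * 1024), ],
                 dec1$pred_mu$val, tolerance = 1e-12)
  # z-averaged KL scalar invariant to replication
  expect_equal(lg4$terms$kl, lg1$terms$kl, tolerance = 1e-10)
  # likelihood accumulates evidence across slices (grows with z)
  expect_equal(lg4$terms$nll_denoise, 4 * lg1$terms$nll_denoise,
               tolerance = 1e-8)
})

test_that("graph-side losses are finite and differentiable at random init", {
  st <- test_stack(96, 96, seed = 8)
  task <- mix_task(2, mode = "I", noise = noise_spec(8, 2))
  smp <- make_patch_sampler(st, task, 32, L = 1, frame_seed = 2)
  nm <- pg_noise_model(2, 8)
  for (s in 1:5) {
    m <- tiny_model(L = 1, levels = 2, patch = 32, seed = s)
    b <- smp(2, s)
    stp <- vsplit:::.train_step(m, b, nm, loss_config(), step_seed = s)
    expect_true(is.finite(stp$loss))
    gs <- unlist(lapply(stp$grads, function(g) if (!is.null(g)) sum(abs(g))))
    expect_true(all(is.finite(gs)))
    expect_gt(sum(gs), 0)
  }
})
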