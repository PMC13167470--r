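# the reverse-mode engine underpinning the network: finite-difference
# gradient checks over a graph exercising every op, plus semantics of the
# index-based ops against naive array implementations

build_toy_graph <- function(params, x_arr, ctx_arr, tgt, eps, nmod = NULL) {
  n <- dim(x_arr)[3L]; h <- dim(x_arr)[1L]; w <- dim(x_arr)[2L]
  Zc <- ncol(eps)
  tape <- vsplit:::ad_tape()
  P <- lapply(params, function(v) vsplit:::ad_param(tape, v))
  x <- vsplit:::ad_const(tape, matrix(as.vector(x_arr), ncol = 1L),
                         n = n, h = h, w = w)
  cx <- vsplit:::ad_const(tape, matrix(as.vector(ctx_arr), ncol = 1L),
                          n = n, h = h, w = w)
  e0 <- vsplit:::ad_relu(tape, vsplit:::ad_conv2d(tape, x, P$w1, P$b1))
  e0 <- vsplit:::ad_relu(tape, vsplit:::ad_conv2d(tape, e0, P$w2, P$b2))
  pooled <- vsplit:::ad_avgpool2(tape, e0)
  pad <- vsplit:::ad_pad_center(tape, pooled, h, w)
  br <- vsplit:::ad_relu(tape, vsplit:::ad_conv2d(tape, cx, P$w1, P$b1))
  f <- vsplit:::ad_relu(tape, vsplit:::ad_conv2d(
    tape, vsplit:::ad_concat(tape, pad, br), P$wm, P$bm))
  q <- vsplit:::ad_conv2d(tape, f, P$wq, P$bq, kh = 1L, kw = 1L)
  mu <- vsplit:::ad_slice_cols(tape, q, 1L, Zc)
  lv <- vsplit:::ad_clamp(tape, vsplit:::ad_slice_cols(tape, q, Zc + 1L,
                                                       2L * Zc), -8, 8)
  z <- vsplit:::ad_sample_gauss(tape, mu, lv, eps)
  zero <- vsplit:::ad_const(tape, matrix(0, nrow(mu$val), Zc),
                            n = n, h = h, w = w)
  klpx <- vsplit:::ad_kl_diag(tape, mu, lv, zero, zero)
  klz <- vsplit:::ad_zmean(tape, klpx, 2L)
  kl <- vsplit:::ad_scale(tape, vsplit:::ad_sum(
    tape, vsplit:::ad_crop_center(tape, klz, h %/% 2L, w %/% 2L)), 0.01)
  d <- vsplit:::ad_relu(tape, vsplit:::ad_conv2d(tape, z, P$wt, P$bt))
  d <- vsplit:::ad_add(tape, d,
                       vsplit:::ad_upsample2(tape, vsplit:::ad_avgpool2(tape, d)))
  out <- vsplit:::ad_conv2d(tape, d, P$wh, P$bh)
  pmu <- vsplit:::ad_slice_cols(tape, out, 1L, 2L)
  plv <- vsplit:::ad_clamp(tape, vsplit:::ad_slice_cols(tape, out, 3L, 4L),
                           -8, 8)
  lik <- if (is.null(nmod)) {
    vsplit:::ad_sum(tape, vsplit:::ad_gauss_nll(tape, pmu, plv, tgt))
  } else {
    praw <- vsplit:::ad_affine_cols(tape, pmu, c(3, 2), c(50, 40))
    vsplit:::ad_sum(tape, vsplit:::ad_noise_nll(tape, praw, tgt, nmod))
  }
  list(tape = tape, P = P, loss = vsplit:::ad_add(tape, lik, kl))
}

toy_params <- function(C = 3L, Zc = 2L) {
  set.seed(99)
  list(w1 = matrix(rnorm(9 * C, 0, 0.3), 9, C), b1 = matrix(0, 1, C),
       w2 = matrix(rnorm(9 * C * C, 0, 0.2), 9 * C, C),
       b2 = matrix(0.1, 1, C),
       wm = matrix(rnorm(9 * 2 * C * C, 0, 0.2), 9 * 2 * C, C),
       bm = matrix(0, 1, C),
       wq = matrix(rnorm(C * 2 * Zc, 0, 0.3), C, 2 * Zc),
       bq = matrix(0, 1, 2 * Zc),
       wt = matrix(rnorm(9 * Zc * C, 0, 0.3), 9 * Zc, C),
       bt = matrix(0, 1, C),
       wh = matrix(rnorm(9 * C * 4, 0, 0.3), 9 * C, 4),
       bh = matrix(0, 1, 4))
}

test_that("backward pass matches finite differences through every op", {
  set.seed(7)
  n <- 2L; h <- 8L; w <- 8L; Zc <- 2L
  x_arr <- array(rnorm(n * h * w), c(h, w, n))
  ctx_arr <- array(rnorm(n * h * w), c(h, w, n))
  tgt <- matrix(rnorm(n * h * w * 2), n * h * w, 2)
  eps <- matrix(rnorm(n * h * w * Zc), ncol = Zc)
  params <- toy_params()
  for (nmod in list(NULL, pg_noise_model(2, 5))) {
    tgt_use <- if (is.null(nmod)) tgt else abs(tgt) * 10 + 45
    g <- build_toy_graph(params, x_arr, ctx_arr, tgt_use, eps, nmod)
    vsplit:::ad_backward(g$tape, g$loss)
    for (nm in names(params)) {
      an <- g$P[[nm]]$grad
      expect_false(is.null(an), label = paste("grad exists for", nm))
      idxs <- sample(length(params[[nm]]), min(4L, length(params[[nm]])))
      for (i in idxs) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
        fd <- (build_toy_graph(pp, x_arr, ctx_arr, tgt_use, eps,
                               nmod)$loss$val[1L] -
               build_toy_graph(pm, x_arr, ctx_arr, tgt_use, eps,
                               nmod)$loss$val[1L]) / 2e-5
        expect_lt(abs(fd - an[i]), 1e-3 * max(1, abs(fd)))
      }
    }
  }
})

test_that("index-based ops match naive array semantics", {
  set.seed(3)
  n <- 2L; h <- 6L; w <- 4L
  a <- array(rnorm(n * h * w * 3), c(h, w, 3, n))
  X <- matrix(0, n * h * w, 3)
  for (c in 1:3) X[, c] <- as.vector(a[, , c, ])
  tape <- vsplit:::ad_tape()
  x <- vsplit:::ad_const(tape, X, n = n, h = h, w = w)

  pool <- vsplit:::ad_avgpool2(tape, x)
  for (s in 1:n) for (c in 1:3) {
    manual <- vsplit:::block_downscale(a[, , c, s], 2L)
    got <- matrix(pool$val[((s - 1) * (h / 2) * (w / 2) + 1):
                           (s * (h / 2) * (w / 2)), c], h / 2, w / 2)
    expect_equal(got, manual, ignore_attr = TRUE)
  }

  up <- vsplit:::ad_upsample2(tape, pool)
  for (s in 1:n) {
    got <- matrix(up$val[((s - 1) * h * w + 1):(s * h * w), 1], h, w)
    manual <- vsplit:::block_downscale(a[, , 1, s], 2L)[
      rep(seq_len(h / 2), each = 2), rep(seq_len(w / 2), each = 2)]
    expect_equal(got, manual, ignore_attr = TRUE)
  }

  crop <- vsplit:::ad_crop_center(tape, x, 2L, 2L)
  got <- matrix(crop$val[1:4, 2], 2, 2)
  expect_equal(got, a[3:4, 2:3, 2, 1], ignore_attr = TRUE)

  pad <- vsplit:::ad_pad_center(tape, crop, h, w)
  padm <- matrix(pad$val[1:(h * w), 2], h, w)
  expect_equal(padm[3:4, 2:3], a[3:4, 2:3, 2, 1], ignore_attr = TRUE)
  expect_equal(sum(padm != 0), 4L)

  # z-mean over slice pairs (n = 2 volumes of nz = 1? use x with nz = 2)
  zm <- vsplit:::ad_zmean(tape, x, 2L)
  expect_equal(matrix(zm$val[1:(h * w), 1], h, w),
               (a[, , 1, 1] + a[, , 1, 2]) / 2, ignore_attr = TRUE)
})

test_that("conv2d agrees with a direct double-loop convolution", {
  set.seed(11)
  h <- 5L; w <- 7L; cin <- 2L; cout <- 3L
  a <- array(rnorm(h * w * cin), c(h, w, cin))
  X <- matrix(0, h * w, cin)
  for (c in seq_len(cin)) X[, c] <- as.vector(a[, , c])
  Wm <- matrix(rnorm(9 * cin * cout, 0, 0.5), 9 * cin, cout)
  bias <- rnorm(cout)
  tape <- vsplit:::ad_tape()
  x <- vsplit:::ad_const(tape, X, n = 1L, h = h, w = w)
  wt <- vsplit:::ad_param(tape, Wm)
  bs <- vsplit:::ad_param(tape, matrix(bias, 1L))
  out <- vsplit:::ad_conv2d(tape, x, wt, bs)
  # naive: offsets enumerated dx (outer) then dy, both ascending
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  naive <- array(0, c(h, w, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(bias[co], h, w)
    for (k in seq_len(9)) for (ci in seq_len(cin)) {
      shifted <- matrix(0, h, w)
      ys <- seq_len(h) + offs$dy[k]; xs <- seq_len(w) + offs$dx[k]
      vy <- ys >= 1 & ys <= h; vx <- xs >= 1 & xs <= w
      shifted[vy, vx] <- a[ys[vy], xs[vx], ci]
      acc <- acc + shifted * Wm[(k - 1) * cin + ci, co]
    }
    naive[, , co] <- acc
  }
  for (co in seq_len(cout))
    expect_equal(matrix(out$val[, co], h, w), naive[, , co],
                 ignore_attr = TRUE, tolerance = 1e-12)
})
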