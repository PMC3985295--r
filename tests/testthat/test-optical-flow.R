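test_that("derivatives vanish on identical constant frames", {
  f <- matrix(5, 8, 8)
  d <- image_derivatives(f, f)
  expect_equal(d$Ix, matrix(0, 8, 8))
  expect_equal(d$Iy, matrix(0, 8, 8))
  expect_equal(d$It, matrix(0, 8, 8))
})

test_that("derivatives are exact on linear and constant-offset images", {
  n <- 10
  ramp <- matrix(seq_len(n), n, n, byrow = TRUE)  # I(x, y) = x
  d <- image_derivatives(ramp, ramp)
  expect_equal(d$Ix[2:(n - 1), 2:(n - 1)], matrix(1, n - 2, n - 2))
  expect_equal(d$It, matrix(0, n, n))

  c1 <- matrix(3, 6, 6)
  d2 <- image_derivatives(c1, c1 + 0.7)
  expect_equal(d2$It, matrix(0.7, 6, 6))
  expect_equal(d2$Ix, matrix(0, 6, 6))
  expect_equal(d2$Iy, matrix(0, 6, 6))
})

test_that("derivative and flow inputs are validated", {
  expect_error(image_derivatives(matrix(0, 4, 4), matrix(0, 5, 4)),
               "identical dimensions")
  expect_error(image_derivatives(matrix(1, 1, 4), matrix(1, 1, 4)), "2x2")
  bad <- matrix(c(1, NA, 1, 1), 2, 2)
  expect_error(image_derivatives(bad, bad), "non-finite")
  expect_error(flow_config(lambda_reg = 0))
  expect_error(flow_config(blur_sigma = -1))
})

test_that("identical frames give exactly zero flow from zero initialization", {
  f <- make_texture(32, seed = 2)
  fl <- horn_schunck_flow(f, f, flow_config(n_iterations = 10))
  expect_equal(fl$ux, matrix(0, 32, 32))
  expect_equal(fl$uy, matrix(0, 32, 32))
})

test_that("a 1-px translation is recovered within the calibrated band", {
  f1 <- make_texture(64, seed = 1)
  f2 <- shift_x1(f1)
  fl <- horn_schunck_flow(f1, f2, flow_config(n_iterations = 2000))
  expect_true(fl$converged)
  interior <- 5:60
  expect_gt(mean(fl$ux[interior, interior]), 0.7)
  expect_lt(mean(fl$ux[interior, interior]), 1.3)
  expect_lt(mean(abs(fl$uy[interior, interior])), 0.15)
})

test_that("flipping the displacement direction flips the estimated flow", {
  f1 <- make_texture(64, seed = 3)
  cfg <- flow_config(n_iterations = 500)
  fwd <- horn_schunck_flow(f1, shift_x1(f1), cfg)
  bwd <- horn_schunck_flow(shift_x1(f1), f1, cfg)
  interior <- 5:60
  expect_equal(mean(bwd$ux[interior, interior]),
               -mean(fwd$ux[interior, interior]), tolerance = 0.1)
})

test_that("a dominant regularizer freezes the first update near zero", {
  f1 <- make_texture(32, seed = 4)
  f2 <- shift_x1(f1)
  fl <- horn_schunck_flow(f1, f2, flow_config(lambda_reg = 1e6,
                                              n_iterations = 1))
  d <- image_derivatives(f1, f2)
  bound <- max(abs(d$Ix * d$It), abs(d$Iy * d$It)) / 1e6
  expect_lte(max(abs(fl$ux)), bound + 1e-12)
  expect_lte(max(abs(fl$uy)), bound + 1e-12)
})

test_that("the smoothness-plus-data objective is nonincreasing over iterates", {
  f1 <- make_texture(32, seed = 6)
  f2 <- shift_x1(f1)
  d <- image_derivatives(f1, f2)
  lambda <- 100
  obj <- vapply(1:40, function(k) {
    fl <- horn_schunck_flow(f1, f2, flow_config(lambda_reg = lambda,
                                                n_iterations = k,
                                                convergence_tol = 1e-12))
    flow_objective(fl, d, lambda)
  }, numeric(1))
  expect_true(all(diff(obj) <= 1e-8 * abs(obj[-length(obj)])))
})

test_that("half-wave rectification splits and reconstructs exactly", {
  set.seed(7)
  ux <- matrix(rnorm(64), 8, 8)
  uy <- matrix(rnorm(64), 8, 8)
  ch <- rectify_channels(list(ux = ux, uy = uy))
  for (m in ch) expect_true(all(m >= 0))
  expect_identical(ch$ux_pos - ch$ux_neg, ux)
  expect_identical(ch$uy_pos - ch$uy_neg, uy)
  expect_equal(rectify_channels(list(ux = matrix(c(2, -3), 1),
                                     uy = matrix(0, 1, 2)))$ux_pos[1, ],
               c(2, 0))
  zero <- rectify_channels(list(ux = matrix(0, 4, 4), uy = matrix(0, 4, 4)))
  for (m in zero) expect_equal(m, matrix(0, 4, 4))
})

test_that("blurring conserves mass and respects the identity settings", {
  z <- list(ux_pos = matrix(0, 8, 8), ux_neg = matrix(0, 8, 8),
            uy_pos = matrix(0, 8, 8), uy_neg = matrix(0, 8, 8))
  out <- blur_and_normalize(z, flow_config())
  for (m in out) expect_equal(m, matrix(0, 8, 8))

  set.seed(8)
  r <- lapply(1:4, function(i) matrix(runif(64), 8, 8))
  names(r) <- c("ux_pos", "ux_neg", "uy_pos", "uy_neg")
  ident <- blur_and_normalize(r, flow_config(blur_sigma = 0,
                                             normalization = "none"))
  expect_equal(ident$ubx_pos, r$ux_pos)
  expect_equal(ident$uby_neg, r$uy_neg)

  # unit-mass kernel: an impulse spreads but its sum is conserved
  imp <- matrix(0, 15, 15)
  imp[8, 8] <- 3
  blurred <- blur_and_normalize(list(ux_pos = imp, ux_neg = imp * 0,
                                     uy_pos = imp * 0, uy_neg = imp * 0),
                                flow_config(blur_sigma = 1,
                                            normalization = "none"))
  expect_equal(sum(blurred$ubx_pos), 3, tolerance = 1e-12)
  expect_lt(max(blurred$ubx_pos), 3)

  neg <- r
  neg$ux_pos[1, 1] <- -1
  expect_error(blur_and_normalize(neg), "nonnegative")
})

test_that("frame-max normalization maps channels into [0, 1] keeping ratios", {
  set.seed(9)
  r <- list(ux_pos = matrix(runif(64, 0, 5), 8, 8),
            ux_neg = matrix(runif(64, 0, 2), 8, 8),
            uy_pos = matrix(runif(64, 0, 1), 8, 8),
            uy_neg = matrix(0, 8, 8))
  out <- blur_and_normalize(r, flow_config(blur_sigma = 0))
  expect_equal(max(vapply(out, max, numeric(1))), 1)
  raw <- blur_and_normalize(r, flow_config(blur_sigma = 0,
                                           normalization = "none"))
  mx <- max(vapply(raw, max, numeric(1)))
  # one common divisor for all four channels: relative magnitudes preserved
  expect_equal(out$ubx_neg * mx, raw$ubx_neg)
  expect_equal(out$uby_pos * mx, raw$uby_pos)
})

test_that("sequence channels cover every consecutive pair", {
  cfg <- synth_config(n_frames = 5, noise_sigma = 0, image_size = 32)
  sA <- generate_sequence(cfg, "A", seed = 2)
  ch <- sequence_flow_channels(sA, flow_config())
  expect_length(ch, 4)
  for (c1 in ch) {
    expect_equal(c1$ubx_pos + c1$ubx_neg + c1$uby_pos + c1$uby_neg,
                 matrix(0, 32, 32))
  }
  s2 <- generate_sequence(synth_config(noise_sigma = 0), "B", seed = 2)
  expect_length(sequence_flow_channels(s2, flow_config()), 1)
  expect_error(sequence_flow_channels(array(0, c(8, 8, 1)), flow_config()),
               "at least 2 frames")
})

test_that("class D carries more channel energy than class B at equal seed", {
  cfg <- synth_config(noise_sigma = 0)
  fc <- flow_config()
  energy <- vapply(c("B", "D"), function(cl) {
    s <- generate_sequence(cfg, cl, seed = 21)
    ch <- sequence_flow_channels(s, fc)[[1]]
    mean(ch$ubx_pos + ch$ubx_neg + ch$uby_pos + ch$uby_neg)
  }, numeric(1))
  expect_gt(energy[["D"]], energy[["B"]])
})
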