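test_that("grayscale conversion uses BT.601 luma weights", {
  rgb <- array(0, dim = c(1, 1, 3))
  rgb[1, 1, ] <- c(255, 255, 255)
  expect_equal(to_grayscale(rgb)[1, 1], 255)
  red <- array(0, dim = c(1, 1, 3))
  red[1, 1, 1] <- 255
  expect_equal(to_grayscale(red)[1, 1], 76.245)
  m <- matrix(1:6, 2, 3)
  expect_identical(to_grayscale(m), m)
  expect_error(to_grayscale(array(0, dim = c(2, 2, 4))), "channel")
})

test_that("luminance change is the signed successive-frame difference", {
  a <- matrix(0, 3, 3)
  b <- a
  b[2, 2] <- 250
  expect_equal(luminance_change(a, a), matrix(0, 3, 3))
  expect_equal(luminance_change(a, b)[2, 2], 250)
  expect_equal(luminance_change(b, a)[2, 2], -250)
  expect_error(luminance_change(a, matrix(0, 2, 2)), "dimension")
})

test_that("half-wave rectification splits and sign-inverts polarity", {
  P <- matrix(c(5, -3, 0, 2), 2, 2)
  L <- hwr_split(P)
  expect_equal(L$on, matrix(c(5, 0, 0, 2), 2, 2))
  expect_equal(L$off, matrix(c(0, 3, 0, 0), 2, 2))
  expect_identical(L$stage, "L")
})

test_that("passing coefficient favours clusters over isolated excitation", {
  x <- matrix(0, 12, 12)
  x[4:6, 4:6] <- 90  # 3x3 cluster
  x[10, 10] <- 90    # isolated pixel
  L <- hwr_split(x)
  npc <- passing_coefficient(L, delta_c = 0.01)
  # oracle: ALC by nested-loop convolution, then max-normalization
  alc <- oracle_conv2(x, matrix(1 / 9, 3, 3))
  expect_equal(alc[5, 5], 90)
  expect_equal(alc[10, 10], 10)
  expect_equal(npc$on[5, 5], 90 / (0.01 + 90))
  expect_equal(npc$on[10, 10], 10 / (0.01 + 90))
  expect_equal(npc$on[5, 5], 0.99989, tolerance = 1e-4)
  expect_equal(npc$on[10, 10], 0.11110, tolerance = 1e-4)
})

test_that("passing coefficient handles degenerate and uniform fields", {
  z <- hwr_split(matrix(0, 6, 6))
  npc <- passing_coefficient(z)
  expect_equal(npc$on, matrix(0, 6, 6))
  expect_equal(npc$off, matrix(0, 6, 6))
  u <- hwr_split(matrix(40, 8, 8))
  npc_u <- passing_coefficient(u, delta_c = 0.01)
  expect_equal(npc_u$on[4, 4], 40 / 40.01)
})

test_that("spatial denoising removes isolated excitation via the threshold", {
  x <- matrix(0, 12, 12)
  x[4:6, 4:6] <- 90
  x[10, 10] <- 90
  dn <- spatial_denoise(hwr_split(x), lamina_params(iso_threshold = 10))
  expect_equal(dn$on[10, 10], 0)             # 90 * 0.1111 = 10.0 -> zeroed
  expect_equal(dn$on[5, 5], 90 * 90 / 90.01) # cluster centre survives
  expect_equal(dn$on[5, 5], 89.99, tolerance = 1e-3)
})

test_that("denoising ablation and degenerate input pass through", {
  x <- matrix(c(0, 50, 3, 0), 2, 2)
  L <- hwr_split(x)
  off <- spatial_denoise(L, lamina_params(denoise_enabled = FALSE))
  expect_equal(off$on, L$on)
  expect_identical(off$stage, "DN")
  z <- spatial_denoise(hwr_split(matrix(0, 4, 4)))
  expect_equal(z$on, matrix(0, 4, 4))
})

test_that("lateral inhibition subtracts the delayed surround mean", {
  u8 <- matrix(8, 10, 10)
  DN <- lptcmotion:::polar_pair(u8, u8, "DN")
  zeroes <- lptcmotion:::polar_pair(matrix(0, 10, 10), matrix(0, 10, 10),
                                    "DN")
  # no history: identity
  expect_equal(lateral_inhibition(DN, zeroes)$on, u8)
  # uniform field: surround kernel sums to 1, interior 8 - 0.25 * 8 = 6
  s <- lateral_inhibition(DN, DN, lamina_params(li_weight = 0.25))
  expect_equal(s$on[5, 5], 6)
  # disabled: identity
  off <- lateral_inhibition(DN, DN, lamina_params(li_enabled = FALSE))
  expect_equal(off$on, u8)
})

test_that("pre-processing variants behave like their defining filters", {
  u <- matrix(20, 11, 11)
  Lu <- hwr_split(u)
  p_mean <- lamina_params(preprocessor = "mean")
  expect_equal(apply_preprocessor(Lu, p_mean)$pair$on[6, 6], 20)
  p_dog <- lamina_params(preprocessor = "dog")
  expect_equal(apply_preprocessor(Lu, p_dog)$pair$on[6, 6], 0,
               tolerance = 1e-10)
  salt <- matrix(0, 9, 9)
  salt[5, 5] <- 255
  p_med <- lamina_params(preprocessor = "median")
  expect_equal(apply_preprocessor(hwr_split(salt), p_med)$pair$on,
               matrix(0, 9, 9))
  # fdsr: first step passes the onset, a sustained signal is suppressed
  p_fdsr <- lamina_params(preprocessor = "fdsr")
  st1 <- apply_preprocessor(Lu, p_fdsr)
  expect_equal(st1$pair$on, u)
  st2 <- apply_preprocessor(Lu, p_fdsr, st1$state)
  expect_equal(st2$pair$on, matrix(0, 11, 11))
})

test_that("lamina invariants hold on random fields", {
  set.seed(42)
  for (i in 1:5) {
    P <- matrix(rnorm(64, sd = 60), 8, 8)
    L <- hwr_split(P)
    npc <- passing_coefficient(L)
    expect_true(all(npc$on >= 0 & npc$on < 1))
    expect_true(all(npc$off >= 0 & npc$off < 1))
    dn <- spatial_denoise(L, lamina_params(iso_threshold = 0))
    expect_true(all(dn$on <= L$on + 1e-12))
    prev <- hwr_split(matrix(rnorm(64, sd = 60), 8, 8))
    s <- lateral_inhibition(dn, lptcmotion:::polar_pair(prev$on, prev$off,
                                                        "DN"))
    expect_true(all(s$on >= 0))
    expect_true(all(s$off >= 0))
  }
})

test_that("compiled convolution matches the nested-loop oracle to 1e-10", {
  set.seed(1)
  kernels <- list(matrix(1 / 9, 3, 3), lptcmotion:::ring_kernel(),
                  gaussian_kernel(5, 5), gaussian_kernel(1, 3, FALSE),
                  matrix(runif(9), 3, 3))
  for (k in kernels) {
    x <- matrix(runif(64, -50, 50), 8, 8)
    expect_equal(conv2_replicate(x, k), oracle_conv2(x, k),
                 tolerance = 1e-10)
  }
  expect_error(conv2_replicate(matrix(0, 4, 4), matrix(1, 2, 2)), "odd")
})
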