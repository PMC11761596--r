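pp <- lptcmotion:::polar_pair

quad_const <- function(U = 0, D = 0, R = 0, L = 0, dim = c(3, 3),
                       stage = "T4") {
  lptcmotion:::directional_quad(matrix(U, dim[1], dim[2]),
                                matrix(D, dim[1], dim[2]),
                                matrix(R, dim[1], dim[2]),
                                matrix(L, dim[1], dim[2]), stage)
}

test_that("T5 mirrors the T4 structure on the OFF pathway", {
  now <- matrix(0, 1, 7)
  now[1, 4] <- 1
  delayed <- matrix(0, 1, 7)
  delayed[1, 3] <- 1  # dark bar stepping right by sd per delay
  q <- t5_correlate(now, delayed, sd = 1)
  expect_gt(sum(q$R), 0)
  expect_equal(sum(q$R), -sum(q$L))
  static <- t5_correlate(now, now, sd = 1)
  for (d in c("U", "D", "R", "L")) expect_equal(sum(abs(static[[d]])), 0)
})

test_that("LPTC convergence rectifies before the fractional power", {
  zc <- pp(matrix(0, 3, 3), matrix(0, 3, 3), "C")
  lp <- lptc_converge(quad_const(U = 4), quad_const(stage = "T5"), zc)
  expect_equal(lp$U[1, 1], 2)  # sqrt(4)
  # ON term rectified to zero when the contrast signal exceeds the motion
  c2 <- pp(matrix(2, 3, 3), matrix(0, 3, 3), "C")
  lp2 <- lptc_converge(quad_const(U = 1), quad_const(stage = "T5"), c2)
  expect_equal(lp2$U[1, 1], 0)
  # contrast ablation: C = 0, T4 = T5 = 0.25 -> 0.5 + 0.5
  lp3 <- lptc_converge(quad_const(U = 0.25), quad_const(U = 0.25,
                                                        stage = "T5"), zc)
  expect_equal(lp3$U[1, 1], 1)
  # all maps nonnegative for arbitrary signed input
  set.seed(9)
  r <- function() matrix(rnorm(9), 3, 3)
  lp4 <- lptc_converge(
    lptcmotion:::directional_quad(r(), r(), r(), r(), "T4"),
    lptcmotion:::directional_quad(r(), r(), r(), r(), "T5"),
    pp(r(), r(), "C"))
  for (d in c("U", "D", "R", "L")) expect_true(all(lp4[[d]] >= 0))
})

test_that("LPi opponency computes the field-summed opponent responses", {
  q <- quad_const(U = 1, D = 1, stage = "LPTC")
  expect_equal(unname(lpi_opponency(q)["vs"]), 0)
  q2 <- quad_const(stage = "LPTC")
  q2$R[2, 2] <- 1
  q2$L[2, 2] <- -1
  expect_equal(unname(lpi_opponency(q2)["hs"]), 2)
  expect_equal(unname(lpi_opponency(quad_const(stage = "LPTC"))),
               c(0, 0))
})

test_that("direction decoding follows the sign convention", {
  expect_equal(decide_direction(5, 0.1), "up")
  expect_equal(decide_direction(-5, 0.1), "down")
  expect_equal(decide_direction(0, -3), "left")
  expect_equal(decide_direction(0.1, 3), "right")
  expect_equal(decide_direction(0, 0), "none")
  expect_equal(decide_direction(1e-12, 1e-12, epsilon = 1e-9), "none")
  expect_equal(decide_direction(2, -2), "up")  # tie -> vertical channel
})

test_that("a static sequence yields an exactly null response", {
  frames <- array(rep(matrix(runif(30 * 40, 0, 255), 30, 40), 5),
                  dim = c(30, 40, 5))
  out <- run_model(frame_sequence(frames, 30))
  expect_equal(out$vs, rep(0, 3))
  expect_equal(out$hs, rep(0, 3))
  expect_true(all(out$decision == "none"))
})

test_that("the model decodes translating motion in all four directions", {
  for (dir in c("up", "down", "left", "right")) {
    out <- run_model(render_sequence(small_motion_spec(dir)))
    expect_true(all(out$decision == dir))
    # the orthogonal channel is comparatively silent
    if (dir %in% c("up", "down")) {
      expect_lt(sum(abs(out$hs)), 0.05 * sum(abs(out$vs)))
    } else {
      expect_lt(sum(abs(out$vs)), 0.05 * sum(abs(out$hs)))
    }
  }
})

test_that("mirroring the stimulus negates the opposing channel", {
  s <- render_sequence(small_motion_spec("right"))
  mir <- frame_sequence(s$frames[, dim(s$frames)[2]:1, ], s$frame_rate)
  o <- run_model(s)
  om <- run_model(mir)
  expect_equal(om$hs, -o$hs, tolerance = 1e-6)
  expect_equal(om$vs, o$vs, tolerance = 1e-6)
  sv <- render_sequence(small_motion_spec("down"))
  mv <- frame_sequence(sv$frames[dim(sv$frames)[1]:1, , ], sv$frame_rate)
  ov <- run_model(sv)
  omv <- run_model(mv)
  expect_equal(omv$vs, -ov$vs, tolerance = 1e-6)
})

test_that("compiled and reference engines agree to floating-point accuracy", {
  set.seed(12)
  fr <- array(runif(28 * 34 * 6, 0, 255), c(28, 34, 6))
  seq <- frame_sequence(fr, 30)
  for (par in list(model_params(),
                   model_variant_params("model1_no_contrast"),
                   model_variant_params("model2_no_denoise"),
                   model_params(lamina = lamina_params(li_enabled = FALSE)),
                   model_params(medulla = medulla_params(delay_frames = 2,
                                                         sd = 2)))) {
    a <- run_model(seq, par, engine = "cpp")
    b <- run_model(seq, par, engine = "r")
    # vs/hs are near-cancelling field sums of ~1e3 rectified terms, so the
    # comparison scale is the summed magnitude, not the opponent residual
    expect_lt(max(abs(a$vs - b$vs)), 1e-8)
    expect_lt(max(abs(a$hs - b$hs)), 1e-8)
  }
})

test_that("ablation flags bit-equal the named model variants", {
  seq <- render_sequence(small_motion_spec("up"))
  seq <- add_noise(seq, noise_spec("salt_pepper", spn_ratio = 0.02,
                                   seed = 7L))
  flag1 <- model_params(medulla = medulla_params(contrast_enabled = FALSE))
  a <- run_model(seq, flag1)
  b <- run_model(seq, model_variant_params("model1_no_contrast"))
  expect_identical(a$vs, b$vs)
  expect_identical(a$hs, b$hs)
  expect_identical(a$decision, b$decision)
  flag2 <- model_params(lamina = lamina_params(denoise_enabled = FALSE))
  a2 <- run_model(seq, flag2)
  b2 <- run_model(seq, model_variant_params("model2_no_denoise"))
  expect_identical(a2$vs, b2$vs)
  expect_identical(a2$hs, b2$hs)
  expect_identical(a2$decision, b2$decision)
})

test_that("run_model validates its input and honours variants", {
  expect_error(run_model(frame_sequence(array(0, c(4, 4, 2)), 30)),
               "at least 3 frames")
  seq <- render_sequence(small_motion_spec("left", frame_count = 5))
  out <- run_model(seq, model_variant_params("model6_mean"))
  expect_identical(attr(out, "engine"), "r")
  expect_true(all(out$decision == "left"))
  expect_error(run_model(seq, model_variant_params("model3_dog"),
                         engine = "cpp"), "cluster")
})
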