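test_that("rendered object advances by velocity/frame_rate and wraps", {
  spec <- study_stimulus_spec(250, "up", frame_count = 100)
  seq <- render_sequence(spec)
  expect_equal(n_frames(seq), 100)
  expect_equal(dim(seq$frames)[1:2], c(250, 500))
  step <- 2000 / 30
  row0 <- floor((250 - 100) / 2)
  for (t in c(1, 2, 3, 40, 100)) {
    f <- get_frame(seq, t)
    # exactly object_width * object_height object pixels, wrap included
    expect_equal(count_pixels(f, 250), 100 * 50)
    rows_expected <- (round(row0 - step * (t - 1)) +
                        seq_len(100) - 1) %% 250 + 1
    expect_setequal(which(rowSums(f == 250) > 0), rows_expected)
  }
  # per-frame displacement 2000/30 = 66.67 px
  expect_equal(step, 66.6667, tolerance = 1e-4)
})

test_that("zero velocity gives identical frames; rendering is deterministic", {
  spec <- stimulus_spec(field_width = 60, field_height = 40,
                        object_width = 10, object_height = 12,
                        direction = "right", object_velocity = 0,
                        frame_count = 5)
  seq <- render_sequence(spec)
  for (t in 2:5) {
    expect_identical(get_frame(seq, t), get_frame(seq, 1))
  }
  expect_identical(render_sequence(spec)$frames, seq$frames)
})

test_that("displacement larger than the field wraps and conserves pixels", {
  spec <- stimulus_spec(field_width = 50, field_height = 30,
                        object_width = 8, object_height = 6,
                        direction = "down", object_velocity = 40 * 30,
                        frame_count = 2, frame_rate = 30)
  seq <- render_sequence(spec)
  expect_equal(count_pixels(get_frame(seq, 2), 250), 8 * 6)
})

test_that("invalid stimulus specs name the offending field", {
  expect_error(stimulus_spec(object_width = 600), "object_width")
  expect_error(stimulus_spec(frame_count = 1), "frame_count")
  expect_error(stimulus_spec(object_velocity = -1), "object_velocity")
  expect_error(stimulus_spec(object_gray = 300), "object_gray")
})

test_that("noise kind none is the identity and noise is seed-deterministic", {
  seq <- render_sequence(small_motion_spec("up", frame_count = 4))
  expect_identical(add_noise(seq, noise_spec("none")), seq)
  ns <- noise_spec("salt_pepper", spn_ratio = 0.02, seed = 11L)
  expect_identical(add_noise(seq, ns)$frames, add_noise(seq, ns)$frames)
  ng <- noise_spec("gaussian", gn_std = 30, seed = 11L)
  expect_identical(add_noise(seq, ng)$frames, add_noise(seq, ng)$frames)
})

test_that("salt-and-pepper corruption count matches the binomial expectation", {
  frames <- array(100, dim = c(250, 500, 3))
  seq <- frame_sequence(frames, 30)
  noisy <- add_noise(seq, noise_spec("salt_pepper", spn_ratio = 0.04,
                                     seed = 5L))
  for (t in 1:3) {
    n_corrupt <- sum(get_frame(noisy, t) != 100)
    # expectation 125000 * 0.04 = 5000, 4 binomial sd = 4 * 69.3
    expect_lt(abs(n_corrupt - 5000), 4 * sqrt(125000 * 0.04 * 0.96))
    corrupted <- get_frame(noisy, t)[get_frame(noisy, t) != 100]
    expect_true(all(corrupted %in% c(0, 255)))
  }
})

test_that("salt-and-pepper noise of a frame depends only on (seed, t)", {
  short_seq <- frame_sequence(array(100, dim = c(20, 20, 2)), 30)
  long_seq <- frame_sequence(array(100, dim = c(20, 20, 5)), 30)
  ns <- noise_spec("salt_pepper", spn_ratio = 0.3, seed = 3L)
  expect_identical(get_frame(add_noise(short_seq, ns), 2),
                   get_frame(add_noise(long_seq, ns), 2))
})

test_that("gaussian noise respects clipping and its static default", {
  seq <- frame_sequence(array(0, dim = c(30, 30, 4)), 30)
  noisy <- add_noise(seq, noise_spec("gaussian", gn_std = 80, seed = 2L))
  expect_gte(min(noisy$frames), 0)
  expect_lte(max(noisy$frames), 255)
  # static field: the same corruption in every frame of an all-equal input
  expect_identical(get_frame(noisy, 1), get_frame(noisy, 3))
  # per-frame mode: fresh draw each frame
  fresh <- add_noise(seq, noise_spec("gaussian", gn_std = 80,
                                     gn_static = FALSE, seed = 2L))
  expect_false(identical(get_frame(fresh, 1), get_frame(fresh, 2)))
})

test_that("negative noise parameters are rejected", {
  expect_error(noise_spec("salt_pepper", spn_ratio = -0.1), "spn_ratio")
  expect_error(noise_spec("gaussian", gn_std = -2), "gn_std")
})

test_that("sequence save/load round-trips bit-exactly and flags bad input", {
  dir <- withr::local_tempdir()
  seq <- render_sequence(small_motion_spec("right", frame_count = 10))
  save_sequence(seq, dir, spec = small_motion_spec("right", frame_count = 10))
  back <- load_sequence(dir)
  expect_equal(back$frames, seq$frames)
  expect_equal(back$frame_rate, seq$frame_rate)

  file.remove(file.path(dir, "frame_0003.png"))
  expect_error(load_sequence(dir), "missing frame index 3")

  dir2 <- withr::local_tempdir()
  save_sequence(frame_sequence(array(7, c(4, 5, 2)), 30), dir2)
  png::writePNG(matrix(0.5, 6, 6), file.path(dir2, "frame_0002.png"))
  expect_error(load_sequence(dir2), "frame 2 has dimensions")
})

test_that("synthetic panorama is deterministic, sized, and tileable", {
  p1 <- make_synthetic_panorama(seed = 4L)
  p2 <- make_synthetic_panorama(seed = 4L)
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(310, 2048))
  expect_gte(min(p1), 0)
  expect_lte(max(p1), 255)
  # the horizontal seam is no sharper than typical interior column steps
  seam <- mean(abs(p1[, 1] - p1[, 2048]))
  interior <- mean(abs(p1[, -1] - p1[, -2048]))
  expect_lt(seam, 3 * interior)
})

test_that("panorama backgrounds scroll with toroidal wrap", {
  pano <- make_synthetic_panorama(width = 200, height = 60, seed = 9L)
  spec <- stimulus_spec(field_width = 120, field_height = 50,
                        panorama = pano, scroll_velocity = c(200 * 30, 0),
                        object_width = 10, object_height = 10,
                        direction = "right", object_velocity = 0,
                        frame_count = 2, frame_rate = 30)
  seq <- render_sequence(spec)
  # one frame advances the scroll by exactly one panorama period
  expect_identical(get_frame(seq, 2), get_frame(seq, 1))
})
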