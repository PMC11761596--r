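#' Frame sequence container
#'
#' A time-ordered stack of 2-D luminance grids, the model's raw input.
#' Frames are stored as a `height x width x frames` numeric array with
#' values in `[0, 255]`; pixel values may be non-integer (e.g. after
#' Gaussian noise) and are only quantized when written to disk.
#'
#' @param frames numeric array `height x width x frames` (or a list of
#'   equally sized matrices).
#' @param frame_rate frames per second.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate = 30) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share identical dimensions")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be positive")
  }
  if (min(frames) < 0 || max(frames) > 255) {
    stop("frame values must lie in [0, 255]")
  }
  structure(list(frames = frames, frame_rate = frame_rate),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_sequence: %d frames of %d x %d px at %g fps\n",
              d[3], d[1], d[2], x$frame_rate))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq a `frame_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' Extract one frame
#' @param seq a `frame_sequence`.
#' @param t frame index (1-based).
#' @return the frame as a numeric matrix.
#' @export
get_frame <- function(seq, t) seq$frames[, , t]

#' Noise specification
#'
#' @param kind `"none"`, `"salt_pepper"` (per-pixel corruption with the given
#'   ratio, corrupted pixels set to 0 or 255 with equal probability, redrawn
#'   every frame) or `"gaussian"` (zero-mean additive noise of the given
#'   standard deviation, clipped to `[0, 255]`).
#' @param spn_ratio corruption probability per pixel, in `[0, 1]`.
#' @param gn_std Gaussian noise standard deviation (grey levels).
#' @param gn_static draw the Gaussian noise field once per sequence and add
#'   the same field to every frame (the default, matching the benchmark
#'   datasets, whose Gaussian corruption is a static property of the scene
#'   that frame differencing largely cancels), or redraw it per frame
#'   (`FALSE`, temporally white noise).
#' @param seed integer seed; the noise of frame `t` depends only on
#'   `(seed, t)`, so identical seeds give identical output.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "salt_pepper", "gaussian"),
                       spn_ratio = 0, gn_std = 0, gn_static = TRUE,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(spn_ratio) || spn_ratio < 0 || spn_ratio > 1) {
    stop("spn_ratio must lie in [0, 1]")
  }
  if (!is.numeric(gn_std) || gn_std < 0) {
    stop("gn_std must be >= 0")
  }
  structure(list(kind = kind, spn_ratio = spn_ratio, gn_std = gn_std,
                 gn_static = isTRUE(gn_static), seed = as.integer(seed)),
            class = "noise_spec")
}

#' Synthetic stimulus specification
#'
#' Describes a translating solid rectangle over a solid grey or scrolling
#' panoramic background. Sizes are given as `object_height x object_width`
#' (rows x columns); the motion direction is one of up/down/left/right with
#' "up" meaning decreasing row index. Object positions are accumulated in
#' floating point and rounded only at rasterization; positions wrap
#' toroidally so the object stays in view for the whole sequence.
#'
#' @param field_width,field_height visual field size in pixels.
#' @param background_gray solid background grey value in `[0, 255]`, ignored
#'   when a `panorama` is supplied.
#' @param panorama optional background image (matrix, values in `[0, 255]`)
#'   at least as large as the field; scrolled by `scroll_velocity` with
#'   toroidal wrap.
#' @param scroll_velocity background scroll velocity `c(vx, vy)` in
#'   pixels/second (positive = rightward / downward scene motion).
#' @param object_gray object grey value in `[0, 255]`.
#' @param object_width,object_height object size in pixels.
#' @param direction `"up"`, `"down"`, `"left"` or `"right"`.
#' @param object_velocity object speed in pixels/second.
#' @param frame_count number of frames (>= 2).
#' @param frame_rate frames per second.
#' @param noise a [noise_spec()] applied by [add_noise()] when rendering via
#'   [render_sequence()] with `apply_noise = TRUE`.
#' @param seed integer seed recorded with the spec (rendering itself is
#'   deterministic; the seed feeds the noise stage).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(field_width = 500, field_height = 250,
                          background_gray = 1, panorama = NULL,
                          scroll_velocity = c(0, 0), object_gray = 250,
                          object_width = 50, object_height = 100,
                          direction = c("up", "down", "left", "right"),
                          object_velocity = 2000, frame_count = 100,
                          frame_rate = 30, noise = noise_spec("none"),
                          seed = 1L) {
  direction <- match.arg(direction)
  spec <- structure(
    list(field_width = as.integer(field_width),
         field_height = as.integer(field_height),
         background_gray = background_gray, panorama = panorama,
         scroll_velocity = scroll_velocity, object_gray = object_gray,
         object_width = as.integer(object_width),
         object_height = as.integer(object_height), direction = direction,
         object_velocity = object_velocity,
         frame_count = as.integer(frame_count), frame_rate = frame_rate,
         noise = noise, seed = as.integer(seed)),
    class = "stimulus_spec")
  validate_stimulus_spec(spec)
}

validate_stimulus_spec <- function(spec) {
  fail <- function(field, msg) {
    stop(sprintf("invalid stimulus spec: %s %s", field, msg))
  }
  if (spec$field_width < 1 || spec$field_height < 1) {
    fail("field_width/field_height", "must be positive")
  }
  if (spec$object_width > spec$field_width) {
    fail("object_width", "exceeds field_width")
  }
  if (spec$object_height > spec$field_height) {
    fail("object_height", "exceeds field_height")
  }
  if (spec$object_width < 1 || spec$object_height < 1) {
    fail("object_width/object_height", "must be positive")
  }
  if (spec$frame_count < 2) fail("frame_count", "must be >= 2")
  if (spec$frame_rate <= 0) fail("frame_rate", "must be positive")
  if (spec$object_velocity < 0) fail("object_velocity", "must be >= 0")
  if (length(spec$scroll_velocity) != 2 || !is.numeric(spec$scroll_velocity)) {
    fail("scroll_velocity", "must be c(vx, vy) in pixels/second")
  }
  if (!is.null(spec$panorama)) {
    if (!is.matrix(spec$panorama)) fail("panorama", "must be a matrix")
    if (ncol(spec$panorama) < spec$field_width ||
        nrow(spec$panorama) < spec$field_height) {
      fail("panorama", "must be at least as large as the field")
    }
  } else {
    if (spec$background_gray < 0 || spec$background_gray > 255) {
      fail("background_gray", "must lie in [0, 255]")
    }
  }
  if (spec$object_gray < 0 || spec$object_gray > 255) {
    fail("object_gray", "must lie in [0, 255]")
  }
  if (!inherits(spec$noise, "noise_spec")) fail("noise", "must be a noise_spec")
  spec
}

#' Render a synthetic stimulus sequence
#'
#' Draws `frame_count` frames of the translating rectangle described by the
#' spec. The object advances by `object_velocity / frame_rate` pixels per
#' frame along the stated direction; sub-pixel positions accumulate in
#' floating point and are rounded at rasterization, and positions wrap
#' toroidally so every frame contains exactly
#' `object_width * object_height` object pixels. Panorama backgrounds scroll
#' by their own velocity with toroidal wrap.
#'
#' @param spec a [stimulus_spec()].
#' @param apply_noise also apply `spec$noise` via [add_noise()]?
#' @return a [frame_sequence()].
#' @export
render_sequence <- function(spec, apply_noise = FALSE) {
  spec <- validate_stimulus_spec(spec)
  h <- spec$field_height
  w <- spec$field_width
  nf <- spec$frame_count
  step <- spec$object_velocity / spec$frame_rate
  dir_vec <- switch(spec$direction,
                    up = c(-1, 0), down = c(1, 0),
                    left = c(0, -1), right = c(0, 1))
  # top-left corner of the object, 0-based, centred at t = 1
  row0 <- floor((h - spec$object_height) / 2)
  col0 <- floor((w - spec$object_width) / 2)
  frames <- array(0, dim = c(h, w, nf))
  solid_bg <- if (is.null(spec$panorama)) {
    matrix(spec$background_gray, h, w)
  }
  for (t in seq_len(nf)) {
    bg <- if (is.null(spec$panorama)) solid_bg else background_frame(spec, t)
    r <- round(row0 + dir_vec[1] * step * (t - 1))
    c <- round(col0 + dir_vec[2] * step * (t - 1))
    rows <- (r + seq_len(spec$object_height) - 1) %% h + 1
    cols <- (c + seq_len(spec$object_width) - 1) %% w + 1
    bg[rows, cols] <- spec$object_gray
    frames[, , t] <- bg
  }
  out <- frame_sequence(frames, spec$frame_rate)
  if (apply_noise) out <- add_noise(out, spec$noise)
  out
}

background_frame <- function(spec, t) {
  h <- spec$field_height
  w <- spec$field_width
  if (is.null(spec$panorama)) {
    return(matrix(spec$background_gray, h, w))
  }
  pano <- spec$panorama
  ph <- nrow(pano)
  pw <- ncol(pano)
  dx <- round(spec$scroll_velocity[1] / spec$frame_rate * (t - 1))
  dy <- round(spec$scroll_velocity[2] / spec$frame_rate * (t - 1))
  rows <- (dy + seq_len(h) - 1) %% ph + 1
  cols <- (dx + seq_len(w) - 1) %% pw + 1
  pano[rows, cols]
}

#' Corrupt a frame sequence with noise
#'
#' Salt-and-pepper noise corrupts each pixel independently with probability
#' `spn_ratio`, setting it to 0 or 255 with equal probability, with a fresh
#' draw every frame. Gaussian noise adds zero-mean noise of the given
#' standard deviation per pixel and clips the result to `[0, 255]`, keeping
#' real (unquantized) values; by default (`gn_static = TRUE`) one noise
#' field is drawn per sequence and added to every frame, modelling a static
#' corruption of the scene, while `gn_static = FALSE` redraws it per frame.
#' The RNG is reseeded per frame from `(seed, t)`, so the noise of a frame
#' does not depend on the other frames and identical seeds give identical
#' output.
#'
#' @param seq a [frame_sequence()].
#' @param noise a [noise_spec()].
#' @return a new [frame_sequence()]; `kind = "none"` returns the input
#'   unchanged.
#' @export
add_noise <- function(seq, noise) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(noise, "noise_spec"))
  if (noise$kind == "none") {
    return(seq)
  }
  d <- dim(seq$frames)
  n <- d[1] * d[2]
  frames <- seq$frames
  static_field <- NULL
  if (noise$kind == "gaussian" && noise$gn_static) {
    set.seed(noise$seed)
    static_field <- matrix(rnorm(n, mean = 0, sd = noise$gn_std), d[1], d[2])
  }
  for (t in seq_len(d[3])) {
    f <- frames[, , t]
    if (noise$kind == "salt_pepper") {
      set.seed(noise$seed + (t - 1L))
      corrupt <- which(runif(n) < noise$spn_ratio)
      f[corrupt] <- ifelse(runif(length(corrupt)) < 0.5, 0, 255)
    } else {
      if (is.null(static_field)) {
        set.seed(noise$seed + (t - 1L))
        f <- f + rnorm(n, mean = 0, sd = noise$gn_std)
      } else {
        f <- f + static_field
      }
      f[f < 0] <- 0
      f[f > 255] <- 255
    }
    frames[, , t] <- f
  }
  frame_sequence(frames, seq$frame_rate)
}

#' Deterministic textured panorama
#'
#' Generates a synthetic panoramic background image for scrolling-background
#' stimuli: a band-limited random texture (sinusoids with integer horizontal
#' frequencies, hence exactly horizontally tileable) overlaid with random
#' rectangular blocks that wrap around the horizontal seam. The same seed
#' always produces the same image. This is a synthetic stand-in for
#' photographed panoramic scenes; the default size is 2048 x 310.
#'
#' @param width,height panorama size in pixels.
#' @param seed integer seed.
#' @return a `height x width` matrix with values in `[0, 255]`.
#' @export
make_synthetic_panorama <- function(width = 2048, height = 310, seed = 1L) {
  stopifnot(width >= 2, height >= 2)
  set.seed(as.integer(seed))
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)
  img <- matrix(0, height, width)
  for (k in seq_len(30)) {
    fx <- sample(0:8, 1)
    fy <- sample(0:6, 1)
    amp <- rexp(1)
    phx <- runif(1, 0, 2 * pi)
    phy <- runif(1, 0, 2 * pi)
    img <- img + amp * cos(2 * pi * fx * xs / width + phx) *
      cos(2 * pi * fy * ys / height + phy)
  }
  for (k in seq_len(25)) {
    bw <- sample(20:min(120, width - 1), 1)
    bh <- sample(10:min(80, height - 1), 1)
    x0 <- sample(0:(width - 1), 1)
    y0 <- sample.int(height - bh + 1, 1) - 1
    val <- runif(1, -2, 2)
    cols <- (x0 + seq_len(bw) - 1) %% width + 1
    rows <- y0 + seq_len(bh)
    img[rows, cols] <- img[rows, cols] + val
  }
  rng <- range(img)
  pmin(pmax(255 * (img - rng[1]) / (rng[2] - rng[1]), 0), 255)
}
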