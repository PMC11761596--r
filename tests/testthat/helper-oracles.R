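# Independent brute-force oracles used to pin expected values.

# Nested-loop centred kernel application with replicate padding.
oracle_conv2 <- function(x, k) {
  h <- nrow(x)
  w <- ncol(x)
  hr <- (nrow(k) - 1) / 2
  hc <- (ncol(k) - 1) / 2
  out <- matrix(0, h, w)
  for (r in 1:h) {
    for (c in 1:w) {
      acc <- 0
      for (u in -hr:hr) {
        for (v in -hc:hc) {
          rr <- min(max(r + u, 1), h)
          cc <- min(max(c + v, 1), w)
          acc <- acc + x[rr, cc] * k[u + hr + 1, v + hc + 1]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# Brute-force four-direction pairwise correlator with zero fill.
oracle_correlate <- function(now, delayed, sd) {
  h <- nrow(now)
  w <- ncol(now)
  at <- function(m, r, c) {
    if (r < 1 || r > h || c < 1 || c > w) 0 else m[r, c]
  }
  quad <- list(U = matrix(0, h, w), D = matrix(0, h, w),
               R = matrix(0, h, w), L = matrix(0, h, w))
  for (r in 1:h) {
    for (c in 1:w) {
      quad$U[r, c] <- at(now, r - sd, c) * delayed[r, c] -
        now[r, c] * at(delayed, r - sd, c)
      quad$D[r, c] <- at(now, r + sd, c) * delayed[r, c] -
        now[r, c] * at(delayed, r + sd, c)
      quad$R[r, c] <- at(now, r, c + sd) * delayed[r, c] -
        now[r, c] * at(delayed, r, c + sd)
      quad$L[r, c] <- at(now, r, c - sd) * delayed[r, c] -
        now[r, c] * at(delayed, r, c - sd)
    }
  }
  quad
}

# Count pixels of a frame equal to a grey value.
count_pixels <- function(frame, value) sum(frame == value)

# Small translating-bar sequence kept well inside the field (no wrap, no
# border contact) for symmetry and end-to-end checks.
small_motion_spec <- function(direction, gray = 200, frame_count = 8) {
  vertical <- direction %in% c("up", "down")
  stimulus_spec(field_width = 140, field_height = 140, background_gray = 1,
                object_gray = gray,
                object_width = if (vertical) 16 else 30,
                object_height = if (vertical) 30 else 16,
                direction = direction, object_velocity = 120,
                frame_count = frame_count, frame_rate = 30)
}
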