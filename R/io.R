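#' Save a frame sequence to a directory of PNG files
#'
#' Writes zero-padded numbered 8-bit grayscale PNG files
#' (`frame_0001.png`, ...) plus a `sequence.yml` sidecar recording the frame
#' rate, dimensions and (optionally) the generating stimulus spec. Pixel
#' values are rounded to the nearest integer grey level on disk, so the
#' round trip is bit-exact for integer-valued sequences.
#'
#' @param seq a [frame_sequence()].
#' @param path directory to create/write into.
#' @param spec optional [stimulus_spec()] recorded in the sidecar for
#'   provenance (the panorama image itself is not embedded).
#' @return `path`, invisibly.
#' @export
save_sequence <- function(seq, path, spec = NULL) {
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nf <- n_frames(seq)
  for (t in seq_len(nf)) {
    f <- round(get_frame(seq, t))
    png::writePNG(f / 255, file.path(path, sprintf("frame_%04d.png", t)))
  }
  meta <- list(frame_rate = seq$frame_rate, frame_count = nf,
               height = dim(seq$frames)[1], width = dim(seq$frames)[2])
  if (!is.null(spec)) {
    s <- unclass(spec)
    s$panorama <- if (is.null(s$panorama)) NULL else "<external image>"
    s$noise <- unclass(s$noise)
    meta$spec <- s
  }
  yaml::write_yaml(meta, file.path(path, "sequence.yml"))
  invisible(path)
}

#' Load a frame sequence from a directory of PNG files
#'
#' Expects the layout written by [save_sequence()]: contiguous numbered
#' `frame_NNNN.png` files starting at 1 and a `sequence.yml` sidecar. A gap
#' in the numbering or frames of mixed dimensions raise an error naming the
#' first offending frame index.
#'
#' @param path directory to read.
#' @return a [frame_sequence()].
#' @export
load_sequence <- function(path) {
  if (!dir.exists(path)) stop("no such sequence directory: ", path)
  meta_file <- file.path(path, "sequence.yml")
  frame_rate <- if (file.exists(meta_file)) {
    yaml::read_yaml(meta_file)$frame_rate
  } else {
    30
  }
  files <- list.files(path, pattern = "^frame_\\d+\\.png$")
  if (!length(files)) stop("no frame_NNNN.png files in ", path)
  idx <- sort(as.integer(sub("^frame_(\\d+)\\.png$", "\\1", files)))
  expected <- seq_len(max(idx))
  missing <- setdiff(expected, idx)
  if (length(missing)) {
    stop("missing frame index ", missing[1], " in ", path)
  }
  frames <- vector("list", length(idx))
  ref_dim <- NULL
  for (t in expected) {
    img <- png::readPNG(file.path(path, sprintf("frame_%04d.png", t)))
    if (length(dim(img)) == 3) {  # collapse any colour channels to luma
      img <- to_grayscale(img * 255) / 255
    }
    if (is.null(ref_dim)) {
      ref_dim <- dim(img)
    } else if (!identical(dim(img), ref_dim)) {
      stop("frame ", t, " has dimensions ", paste(dim(img), collapse = "x"),
           ", expected ", paste(ref_dim, collapse = "x"))
    }
    frames[[t]] <- round(img * 255)
  }
  frame_sequence(frames, frame_rate)
}
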