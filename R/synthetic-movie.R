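#' Movie configuration for synthetic imaging data
#'
#' @param frame_size c(Y, X) pixels per plane.
#' @param n_cells number of somata.
#' @param cell_radius_um soma radius (micrometers).
#' @param pixel_size_um micrometers per pixel.
#' @param baseline mean baseline intensity of a soma.
#' @param background background intensity outside somata.
#' @param noise_sd Gaussian shot-noise sd (set 0 for noiseless fixtures).
#' @param drift_amplitude max absolute per-frame rigid drift (pixels,
#'   integer); 0 disables drift.
#' @param seed integer seed.
#' @return object of class `movie_config`.
#' @export
movie_config <- function(frame_size = c(96, 96), n_cells = 10,
                         cell_radius_um = 6, pixel_size_um = 2,
                         baseline = 100, background = 20, noise_sd = 0,
                         drift_amplitude = 0, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  r_px <- cell_radius_um / pixel_size_um
  if (2 * r_px + 2 >= min(frame_size))
    stop("cells do not fit inside the frame", call. = FALSE)
  structure(list(frame_size = as.integer(frame_size),
                 n_cells = as.integer(n_cells),
                 cell_radius_um = cell_radius_um,
                 pixel_size_um = pixel_size_um, baseline = baseline,
                 background = background, noise_sd = noise_sd,
                 drift_amplitude = as.integer(drift_amplitude),
                 seed = as.integer(seed)),
            class = "movie_config")
}

disk_mask <- function(frame_size, center, radius) {
  yy <- matrix(seq_len(frame_size[1]), frame_size[1], frame_size[2])
  xx <- matrix(seq_len(frame_size[2]), frame_size[1], frame_size[2],
               byrow = TRUE)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius^2
}

shift_frame <- function(frame, dy, dx, fill = NULL) {
  if (is.null(fill)) fill <- median(frame)
  out <- matrix(fill, nrow(frame), ncol(frame))
  ys <- seq_len(nrow(frame)); xs <- seq_len(ncol(frame))
  ys_to <- ys + dy; xs_to <- xs + dx
  ok_y <- ys_to >= 1 & ys_to <= nrow(frame)
  ok_x <- xs_to >= 1 & xs_to <= ncol(frame)
  out[ys_to[ok_y], xs_to[ok_x]] <- frame[ys[ok_y], xs[ok_x]]
  out
}

#' Generate a synthetic imaging movie with ground-truth ROIs
#'
#' Places disk-shaped somata without overlap, modulates each by a supplied
#' dF/F trace around its baseline, optionally applies a recorded rigid
#' integer-pixel drift per frame, and adds Gaussian shot noise. The returned
#' ground truth (masks, centers, applied shifts) supports recovery tests of
#' the preprocessing front end.
#'
#' @param mcfg a [movie_config()].
#' @param traces matrix n_cells x T of dF/F values driving soma intensity
#'   (`baseline * (1 + dff)`); rows may be fewer than `n_cells` only if
#'   equal.
#' @return list of class `synthetic_movie`: `frames` (Y x X x T array),
#'   `masks` (labeled integer matrix), `centers`, `shifts` (T x 2, dy/dx),
#'   `mcfg`.
#' @export
generate_movie <- function(mcfg, traces) {
  stopifnot(inherits(mcfg, "movie_config"), is.matrix(traces))
  if (nrow(traces) < mcfg$n_cells)
    stop("need at least `n_cells` trace rows", call. = FALSE)
  fs <- mcfg$frame_size
  r_px <- mcfg$cell_radius_um / mcfg$pixel_size_um
  n_t <- ncol(traces)
  with_substream(mcfg$seed, "movie", {
    centers <- matrix(NA_real_, mcfg$n_cells, 2)
    masks <- matrix(0L, fs[1], fs[2])
    placed <- 0L; tries <- 0L
    while (placed < mcfg$n_cells) {
      tries <- tries + 1L
      if (tries > 2000L)
        stop("could not place cells without overlap", call. = FALSE)
      c_y <- runif(1, r_px + 2, fs[1] - r_px - 1)
      c_x <- runif(1, r_px + 2, fs[2] - r_px - 1)
      if (placed > 0) {
        d2 <- (centers[seq_len(placed), 1] - c_y)^2 +
          (centers[seq_len(placed), 2] - c_x)^2
        if (min(d2) < (2 * r_px + 3)^2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- c(c_y, c_x)
      masks[disk_mask(fs, c(c_y, c_x), r_px)] <- placed
    }
    shifts <- matrix(0L, n_t, 2, dimnames = list(NULL, c("dy", "dx")))
    if (mcfg$drift_amplitude > 0) {
      shifts[, 1] <- sample(seq(-mcfg$drift_amplitude, mcfg$drift_amplitude),
                            n_t, replace = TRUE)
      shifts[, 2] <- sample(seq(-mcfg$drift_amplitude, mcfg$drift_amplitude),
                            n_t, replace = TRUE)
      shifts[1, ] <- 0L
    }
    frames <- array(0, c(fs[1], fs[2], n_t))
    scene0 <- matrix(mcfg$background, fs[1], fs[2])
    for (t in seq_len(n_t)) {
      scene <- scene0
      for (i in seq_len(mcfg$n_cells)) {
        scene[masks == i] <- mcfg$baseline * (1 + traces[i, t])
      }
      if (any(shifts[t, ] != 0L))
        scene <- shift_frame(scene, shifts[t, 1], shifts[t, 2],
                             fill = mcfg$background)
      if (mcfg$noise_sd > 0)
        scene <- scene + matrix(rnorm(length(scene), 0, mcfg$noise_sd),
                                fs[1], fs[2])
      frames[, , t] <- pmax(scene, 0)
    }
    structure(list(frames = frames, masks = masks, centers = centers,
                   shifts = shifts, mcfg = mcfg),
              class = "synthetic_movie")
  })
}

#' Generate synthetic behavior-camera frames
#'
#' Grayscale 300 x 200 (width x height) frame sets per condition (Hit, CR)
#' and task epoch (Pre, Delay, Response), all sharing one static seeded
#' texture plus optional per-frame noise. An optional movement blob can be
#' injected into chosen condition/epoch frames; injected frames are flagged
#' in the ground truth.
#'
#' @param n_frames frames per condition x epoch.
#' @param width,height frame size in pixels.
#' @param noise_sd per-frame Gaussian noise sd (0 = identical frames).
#' @param move_condition,move_epoch where to inject movement (NULL = none).
#' @param move_intensity blob amplitude added to injected frames.
#' @param seed integer seed.
#' @return list of class `frame_set`: `frames[[condition]][[epoch]]` =
#'   height x width x n array, plus `ground_truth` data.frame of per-frame
#'   movement flags.
#' @export
generate_video_frames <- function(n_frames = 10, width = 300, height = 200,
                                  noise_sd = 1, move_condition = NULL,
                                  move_epoch = NULL, move_intensity = 30,
                                  seed = 1L) {
  if (n_frames < 2) stop("need >= 2 frames per condition", call. = FALSE)
  conds <- c("Hit", "CR"); epochs <- c("Pre", "Delay", "Response")
  with_substream(seed, "video", {
    base <- matrix(runif(height * width, 40, 80), height, width)
    blob <- matrix(0, height, width)
    blob[disk_mask(c(height, width), c(height / 2, width / 2), 15)] <-
      move_intensity
    frames <- list(); gt <- NULL
    for (cn in conds) {
      frames[[cn]] <- list()
      for (ep in epochs) {
        inject <- !is.null(move_condition) && cn %in% move_condition &&
          ep %in% (move_epoch %||% epochs)
        arr <- array(0, c(height, width, n_frames))
        for (f in seq_len(n_frames)) {
          fr <- base
          if (inject) fr <- fr + blob
          if (noise_sd > 0)
            fr <- fr + matrix(rnorm(height * width, 0, noise_sd),
                              height, width)
          arr[, , f] <- fr
        }
        frames[[cn]][[ep]] <- arr
        gt <- rbind(gt, data.frame(condition = cn, epoch = ep,
                                   frame = seq_len(n_frames),
                                   movement = inject))
      }
    }
    structure(list(frames = frames, ground_truth = gt,
                   width = width, height = height),
              class = "frame_set")
  })
}

#' Write / read a movie as multi-page TIFF
#'
#' Intensities are scaled to [0, 1] by `scale` for storage and restored on
#' read.
#' @param frames Y x X x T array.
#' @param path file path.
#' @param scale intensity divisor used for storage.
#' @return path (write) or a Y x X x T array (read).
#' @export
write_movie_tiff <- function(frames, path, scale = 2^12) {
  pages <- lapply(seq_len(dim(frames)[3]),
                  function(t) pmin(pmax(frames[, , t] / scale, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, scale = 2^12) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale
  arr
}
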