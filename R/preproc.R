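#' Rigid motion correction by cross-correlation to the mean image
#'
#' Registers every frame to the pixel-wise mean of all frames with a single
#' pass: for each frame the integer-pixel translation (within `max_shift`)
#' maximizing the 2-D cross-correlation with the reference is found via FFT
#' and applied; vacated pixels are filled with the frame median.
#'
#' @param frames Y x X x T array (T >= 2), nonnegative intensities.
#' @param max_shift largest shift magnitude searched (pixels).
#' @param n_passes reference refinement passes. The first pass uses the mean
#'   of the unregistered frames, which is motion-blurred and can bias the
#'   correlation peak by a pixel; a second pass against the mean of the
#'   pass-one output uses a sharp reference and makes integer shifts exact.
#' @return list of class `registered_movie`: `frames` (registered array),
#'   `shifts` (T x 2 total applied dy/dx), `reference` (final). Because the
#'   mean image fixes the spatial anchor only up to a common translation,
#'   shifts are exact relative to one another (compare them anchored to a
#'   reference frame, e.g. `shifts - shifts[1, ]`).
#' @export
register_movie <- function(frames, max_shift = 8, n_passes = 2) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2)
  Y <- dim(frames)[1]; X <- dim(frames)[2]; n_t <- dim(frames)[3]
  shifts <- matrix(0L, n_t, 2, dimnames = list(NULL, c("dy", "dx")))
  if (all(apply(frames, 3, sd) == 0)) {
    warning("constant movie: no registration performed")
    return(structure(list(frames = frames, shifts = shifts,
                          reference = apply(frames, c(1, 2), mean)),
                     class = "registered_movie"))
  }
  dys <- seq(-max_shift, max_shift); dxs <- dys
  row_idx <- ((dys %% Y) + 1); col_idx <- ((dxs %% X) + 1)
  out <- frames
  ref <- NULL
  for (pass in seq_len(n_passes)) {
    ref <- apply(out, c(1, 2), mean)
    fa <- fft(ref - mean(ref))
    moved <- FALSE
    for (t in seq_len(n_t)) {
      fr <- out[, , t]
      cc <- Re(fft(fa * Conj(fft(fr - mean(fr))), inverse = TRUE))
      sub <- cc[row_idx, col_idx]
      ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      dy <- dys[ij[1]]; dx <- dxs[ij[2]]
      if (dy != 0 || dx != 0) {
        out[, , t] <- shift_frame(fr, dy, dx)
        shifts[t, ] <- shifts[t, ] + c(dy, dx)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  structure(list(frames = out, shifts = shifts, reference = ref),
            class = "registered_movie")
}

#' Pixel-wise activity map
#'
#' Scores each pixel by the product of its temporal skewness (transient,
#' positive-going signals) and its mean temporal correlation with the four
#' adjacent pixels (spatially coherent signals), both floored at zero, then
#' rescales the map to [0, 1]. Active somata score far above background;
#' constant movies give an all-zero map.
#'
#' @param frames registered Y x X x T array (or a `registered_movie`).
#' @return Y x X matrix in [0, 1].
#' @export
activity_map <- function(frames) {
  if (inherits(frames, "registered_movie")) frames <- frames$frames
  Y <- dim(frames)[1]; X <- dim(frames)[2]; n_t <- dim(frames)[3]
  mu <- apply(frames, c(1, 2), mean)
  ctr <- sweep(frames, c(1, 2), mu)
  sdv <- sqrt(apply(ctr^2, c(1, 2), mean))
  skew <- apply(ctr^3, c(1, 2), mean) / pmax(sdv, .Machine$double.eps)^3
  skew[sdv == 0] <- 0
  z <- sweep(ctr, c(1, 2), pmax(sdv, .Machine$double.eps), "/")
  z[array(rep(sdv == 0, n_t), dim(z))] <- 0
  ncorr <- matrix(0, Y, X); nn <- matrix(0, Y, X)
  add <- function(a_rows, a_cols, b_rows, b_cols) {
    prod_ <- apply(z[a_rows, a_cols, , drop = FALSE] *
                     z[b_rows, b_cols, , drop = FALSE], c(1, 2), mean)
    ncorr[a_rows, a_cols] <<- ncorr[a_rows, a_cols] + prod_
    nn[a_rows, a_cols] <<- nn[a_rows, a_cols] + 1
  }
  add(1:(Y - 1), 1:X, 2:Y, 1:X)       # neighbor below
  add(2:Y, 1:X, 1:(Y - 1), 1:X)       # neighbor above
  add(1:Y, 1:(X - 1), 1:Y, 2:X)       # right
  add(1:Y, 2:X, 1:Y, 1:(X - 1))       # left
  score <- pmax(skew, 0) * pmax(ncorr / pmax(nn, 1), 0)
  if (max(score) > 0) score <- score / max(score)
  score
}

#' Segment somata from an activity map
#'
#' Binarizes the map with a local adaptive threshold (local-mean window plus
#' offset), labels connected components, and iteratively re-thresholds
#' components larger than the allowed soma area at increasing quantiles of
#' their own scores until pieces fall inside the configured area range;
#' undersized components are discarded.
#'
#' @param map activity map in [0, 1].
#' @param min_area,max_area accepted component area (pixels).
#' @param window local-threshold window half-width (pixels).
#' @param offset threshold offset above the local mean.
#' @param max_iter maximum split iterations per oversized component.
#' @return object of class `roi_set`: `masks` (labeled integer matrix, 0 =
#'   background), `centroids` (n x 2, row/col), `n`.
#' @export
segment_rois <- function(map, min_area = 20, max_area = 500, window = 12,
                         offset = 0.05, max_iter = 5) {
  stopifnot(is.matrix(map))
  if (max(map) == 0) {
    return(structure(list(masks = matrix(0L, nrow(map), ncol(map)),
                          centroids = matrix(numeric(0), 0, 2), n = 0L),
                     class = "roi_set"))
  }
  local_mu <- as.matrix(EBImage::filter2(
    map, matrix(1 / (2 * window + 1)^2, 2 * window + 1, 2 * window + 1)))
  bin <- map > local_mu + offset
  lab <- EBImage::bwlabel(bin)
  accepted <- matrix(0L, nrow(map), ncol(map))
  n_acc <- 0L
  queue <- lapply(seq_len(max(lab)), function(g) which(lab == g))
  depth <- rep(0L, length(queue))
  while (length(queue)) {
    px <- queue[[1]]; d <- depth[1]
    queue <- queue[-1]; depth <- depth[-1]
    area <- length(px)
    if (area < min_area) next
    if (area <= max_area) {
      n_acc <- n_acc + 1L
      accepted[px] <- n_acc
      next
    }
    if (d >= max_iter) next
    thr <- quantile(map[px], 0.5)
    sub <- matrix(FALSE, nrow(map), ncol(map))
    sub[px] <- map[px] > thr
    sl <- EBImage::bwlabel(sub)
    ng <- max(sl)
    if (ng == 0) next
    for (g in seq_len(ng)) {
      queue[[length(queue) + 1L]] <- which(sl == g)
      depth <- c(depth, d + 1L)
    }
  }
  centroids <- matrix(NA_real_, n_acc, 2,
                      dimnames = list(NULL, c("row", "col")))
  for (g in seq_len(n_acc)) {
    idx <- which(accepted == g, arr.ind = TRUE)
    centroids[g, ] <- colMeans(idx)
  }
  structure(list(masks = accepted, centroids = centroids, n = n_acc),
            class = "roi_set")
}

#' Extract somatic and neuropil fluorescence traces
#'
#' For every ROI, the somatic trace is the mean intensity over the ROI mask,
#' and the neuropil trace the mean over an annulus extending
#' `annulus_um[2]` micrometers from the ROI border with all ROI pixels
#' (any label) excluded. If the exclusion empties the annulus it is widened
#' to the nearest non-ROI pixels with a warning.
#'
#' @param frames registered Y x X x T array (or `registered_movie`).
#' @param rois a `roi_set` (or labeled integer matrix).
#' @param pixel_size_um micrometers per pixel.
#' @param annulus_um annulus range from the ROI border (micrometers).
#' @return list of class `fluor_traces`: matrices `F_raw` and `F_neuropil`
#'   (ROI x T), `roi` indices.
#' @export
extract_traces <- function(frames, rois, pixel_size_um = 2,
                           annulus_um = c(0, 15)) {
  if (inherits(frames, "registered_movie")) frames <- frames$frames
  masks <- if (inherits(rois, "roi_set")) rois$masks else rois
  n_roi <- max(masks)
  stopifnot(n_roi >= 1)
  Y <- dim(frames)[1]; X <- dim(frames)[2]; n_t <- dim(frames)[3]
  fm <- matrix(frames, Y * X, n_t)
  any_roi <- masks > 0
  r_px <- max(1L, ceiling(annulus_um[2] / pixel_size_um))
  F_raw <- matrix(NA_real_, n_roi, n_t)
  F_np <- matrix(NA_real_, n_roi, n_t)
  for (g in seq_len(n_roi)) {
    m <- masks == g
    F_raw[g, ] <- colMeans(fm[which(m), , drop = FALSE])
    r <- r_px
    repeat {
      dil <- as.matrix(EBImage::dilate(
        EBImage::Image(m * 1), EBImage::makeBrush(2 * r + 1, "disc"))) > 0
      ann <- dil & !any_roi
      if (any(ann)) break
      r <- r * 2L
      if (r > max(Y, X)) stop("no non-ROI pixels available", call. = FALSE)
      warning("annulus for ROI ", g, " empty after exclusions; widened")
    }
    F_np[g, ] <- colMeans(fm[which(ann), , drop = FALSE])
  }
  structure(list(F_raw = F_raw, F_neuropil = F_np, roi = seq_len(n_roi)),
            class = "fluor_traces")
}

#' Neuropil correction
#'
#' F_corrected(t) = F_raw(t) - coef * F_neuropil(t), removing contamination
#' from out-of-focus processes surrounding the soma.
#'
#' @param traces a `fluor_traces` (or list with `F_raw`, `F_neuropil`).
#' @param coef neuropil contamination coefficient.
#' @return input with `F_corrected` added.
#' @export
neuropil_correct <- function(traces, coef = 0.7) {
  if (!all(dim(traces$F_raw) == dim(traces$F_neuropil)))
    stop("raw and neuropil traces differ in length", call. = FALSE)
  traces$F_corrected <- traces$F_raw - coef * traces$F_neuropil
  traces$neuropil_coef <- coef
  traces
}

#' Baseline estimate and dF/F
#'
#' F0 is the mode of the fluorescence density distribution, estimated as the
#' midpoint of the tallest Freedman-Diaconis histogram bin (default) or the
#' peak of a Gaussian kernel density; dF/F(t) = (F(t) - F0) / F0.
#'
#' @param f fluorescence trace (finite values).
#' @param method mode estimator, "histogram" or "kde".
#' @return list of class `dff_trace`: `dff`, `f0`.
#' @export
compute_dff <- function(f, method = c("histogram", "kde")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(f)))
  if (diff(range(f)) < .Machine$double.eps) {
    f0 <- f[1]
  } else if (method == "histogram") {
    h <- hist(f, breaks = "FD", plot = FALSE)
    i <- which.max(h$counts)
    f0 <- (h$breaks[i] + h$breaks[i + 1]) / 2
  } else {
    d <- density(f)
    f0 <- d$x[which.max(d$y)]
  }
  if (f0 <= 0)
    stop("nonpositive F0; offset the trace before computing dF/F",
         call. = FALSE)
  structure(list(dff = (f - f0) / f0, f0 = f0), class = "dff_trace")
}

#' Remove duplicate ROIs across imaging planes
#'
#' ROI pairs whose fluorescence traces correlate above `r_thresh` and whose
#' XY centroid distance is below `dist_um` are treated as the same neuron
#' sampled twice (e.g. a bright soma visible on two planes); the member with
#' the lower average fluorescence (more likely out of focus) is removed,
#' repeatedly, until no pair violates. Equal means keep the lower index.
#'
#' @param f_mat ROI x T fluorescence matrix.
#' @param centroids_um ROI x 2 XY centroids (micrometers).
#' @param r_thresh correlation threshold.
#' @param dist_um XY distance threshold (micrometers).
#' @return integer indices of retained ROIs.
#' @export
remove_duplicates <- function(f_mat, centroids_um, r_thresh = 0.5,
                              dist_um = 12.5) {
  stopifnot(nrow(f_mat) == nrow(centroids_um))
  keep <- seq_len(nrow(f_mat))
  if (length(keep) < 2) return(keep)
  C <- suppressWarnings(cor(t(f_mat)))
  D <- as.matrix(dist(centroids_um))
  mf <- rowMeans(f_mat)
  repeat {
    viol <- which(C[keep, keep, drop = FALSE] > r_thresh &
                    D[keep, keep, drop = FALSE] < dist_um, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (!nrow(viol)) break
    cand <- unique(as.vector(viol))
    cand_glob <- keep[cand]
    # drop the dimmest ROI involved in any violation; ties -> higher index
    ord <- order(mf[cand_glob], -cand_glob)
    keep <- setdiff(keep, cand_glob[ord[1]])
  }
  keep
}
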