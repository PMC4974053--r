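#' Trial-type selectivity index
#'
#' SI = (R_pref - R_non-pref) / (R_pref + R_non-pref), where R is each
#' neuron's time-integrated baseline-subtracted response magnitude
#' (sign-flipped for suppressed neurons, rectified at zero) over the
#' stimulus-through-response window, averaged over correct trials of each
#' trial type. SI is 0 for unselective and 1 for fully selective neurons.
#'
#' @param traces a `trial_traces`.
#' @param sig a `significance_result` (for response directions); only
#'   neurons listed are scored (default all, direction "enhanced").
#' @return data.frame: neuron, r_hit, r_cr, preferred, si (NA where
#'   undefined).
#' @export
compute_selectivity <- function(traces, sig = NULL) {
  tab <- traces$table
  time_s <- traces$time_s
  dt <- time_s[2] - time_s[1]
  n_neur <- dim(traces$dff)[1]
  direction <- rep("enhanced", n_neur)
  if (!is.null(sig)) direction <- ifelse(is.na(sig$neurons$direction),
                                         "enhanced", sig$neurons$direction)
  base_idx <- which(time_s < 0)
  resp_one_type <- function(type) {
    trials <- which(tab$outcome == type)
    if (!length(trials)) return(rep(NA_real_, n_neur))
    vals <- matrix(NA_real_, n_neur, length(trials))
    for (k in seq_along(trials)) {
      tr <- trials[k]
      win <- which(time_s >= 0 & time_s < tab$t_spout_out[tr])
      x <- matrix(traces$dff[, tr, ], n_neur, length(time_s))
      b <- rowMeans(x[, base_idx, drop = FALSE], na.rm = TRUE)
      vals[, k] <- rowSums(x[, win, drop = FALSE] - b, na.rm = TRUE) * dt
    }
    rowMeans(vals, na.rm = TRUE)
  }
  r_hit <- resp_one_type("hit")
  r_cr <- resp_one_type("CR")
  flip <- direction == "suppressed"
  r_hit[flip] <- -r_hit[flip]
  r_cr[flip] <- -r_cr[flip]
  r_hit <- pmax(r_hit, 0); r_cr <- pmax(r_cr, 0)
  preferred <- ifelse(r_hit >= r_cr, "hit", "CR")  # ties toward hit
  r_pref <- pmax(r_hit, r_cr); r_non <- pmin(r_hit, r_cr)
  si <- ifelse(r_pref + r_non > 0, (r_pref - r_non) / (r_pref + r_non),
               NA_real_)
  data.frame(neuron = seq_len(n_neur), r_hit = r_hit, r_cr = r_cr,
             preferred = preferred, si = si, stringsAsFactors = FALSE)
}

#' Orientation selectivity index
#'
#' OSI = (R_pref - R_orth) / (R_pref + R_orth), with the preferred
#' orientation taken as the argmax response and R_orth the response at the
#' orthogonal orientation (preferred + 90 degrees, modulo 180).
#'
#' @param responses integrated responses per orientation (nonnegative).
#' @param orientations_deg matching orientations in degrees.
#' @return list: osi, theta_pref_deg, r_pref, r_orth (osi NA when the
#'   denominator is 0).
#' @export
compute_osi <- function(responses, orientations_deg) {
  stopifnot(length(responses) == length(orientations_deg))
  i_pref <- which.max(responses)
  theta <- orientations_deg[i_pref]
  orth <- (theta + 90) %% 180
  i_orth <- which.min(abs((orientations_deg - orth + 90) %% 180 - 90))
  r_pref <- responses[i_pref]; r_orth <- responses[i_orth]
  osi <- if (r_pref + r_orth > 0) (r_pref - r_orth) / (r_pref + r_orth)
         else NA_real_
  list(osi = osi, theta_pref_deg = theta, r_pref = r_pref, r_orth = r_orth)
}

#' Response onset latency of a mean trace
#'
#' Linearly interpolates the trial-averaged dF/F to `up_rate` Hz and finds
#' the first sample of the earliest run of at least `run_s` seconds during
#' which every sample is more than 1 baseline SD above (or below) the mean
#' baseline dF/F. The search starts at stimulus onset (t = 0).
#'
#' @param mean_trace trial-averaged dF/F.
#' @param time_s sample times (s); baseline = samples with t < 0.
#' @param up_rate upsampling rate (Hz).
#' @param run_s required suprathreshold duration (s).
#' @param n_sigma threshold in baseline SDs.
#' @return latency in seconds, or NA when no qualifying run exists.
#' @export
estimate_latency <- function(mean_trace, time_s, up_rate = 1000,
                             run_s = 1, n_sigma = 1) {
  ok <- is.finite(mean_trace)
  mean_trace <- mean_trace[ok]; time_s <- time_s[ok]
  base <- mean_trace[time_s < 0]
  if (length(base) < 3) stop("baseline needs >= 3 samples", call. = FALSE)
  mu <- mean(base); sigma <- sd(base)
  tt <- seq(min(time_s), max(time_s), by = 1 / up_rate)
  y <- approx(time_s, mean_trace, xout = tt)$y
  post <- tt >= 0
  tt <- tt[post]; y <- y[post]
  need <- as.integer(run_s * up_rate)
  for (dir in c(1, -1)) {
    runs <- true_runs(dir * (y - mu) > n_sigma * sigma, min_len = need)
    if (nrow(runs)) {
      cand <- tt[runs[1, 1]]
      if (!exists("best", inherits = FALSE) || cand < best) best <- cand
    }
  }
  if (exists("best", inherits = FALSE)) best else NA_real_
}

#' First mode of a population latency distribution
#'
#' Gaussian kernel density (Silverman's rule-of-thumb bandwidth) over the
#' latencies; the summary is the smallest-latency local maximum whose height
#' exceeds `min_height_frac` of the global density maximum — robust to the
#' long right tail of skewed latency distributions.
#'
#' @param latencies latencies in seconds (NAs dropped).
#' @param min_height_frac minimum relative height for a mode.
#' @return latency of the first mode (s).
#' @export
population_modal_latency <- function(latencies, min_height_frac = 0.1) {
  x <- latencies[is.finite(latencies)]
  if (length(x) < 2) stop("need >= 2 finite latencies", call. = FALSE)
  d <- density(x, bw = "nrd0")
  y <- d$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  is_max[y < min_height_frac * max(y)] <- FALSE
  idx <- which(is_max)
  if (!length(idx)) idx <- which.max(y)
  d$x[idx[1]]
}

#' Delay modulation of integrated responses
#'
#' For each neuron, fits a first-order polynomial (least squares) to the
#' integrated trial-averaged dF/F (stimulus onset to spout extension) as a
#' function of delay duration, and summarizes a population by
#' DMI = (n_pos - n_neg)/(n_pos + n_neg) for enhanced populations and its
#' negation for suppressed populations (n_pos/n_neg = neurons with
#' positive/negative slope; exact zeros count in neither).
#'
#' @param traces a `trial_traces`.
#' @param outcome trial outcomes included (default correct trials).
#' @return data.frame: neuron, slope.
#' @export
delay_modulation <- function(traces, outcome = c("hit", "CR")) {
  tab <- traces$table
  time_s <- traces$time_s
  dt <- time_s[2] - time_s[1]
  delays <- sort(unique(tab$delay_s))
  if (length(delays) < 2) stop("need >= 2 delay durations", call. = FALSE)
  n_neur <- dim(traces$dff)[1]
  integ <- matrix(NA_real_, n_neur, length(delays))
  for (di in seq_along(delays)) {
    keep <- tab$outcome %in% outcome & tab$delay_s == delays[di]
    if (!any(keep)) next
    win <- which(time_s >= 0 & time_s < 2 + delays[di])
    M <- apply(traces$dff[, keep, win, drop = FALSE], c(1, 3), mean,
               na.rm = TRUE)
    integ[, di] <- rowSums(M, na.rm = TRUE) * dt
  }
  slope <- apply(integ, 1, function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 2) return(NA_real_)
    coef(lm(y[ok] ~ delays[ok]))[2]
  })
  data.frame(neuron = seq_len(n_neur), slope = as.numeric(slope))
}

#' @rdname delay_modulation
#' @param slopes per-neuron slopes.
#' @param direction "enhanced" or "suppressed" population.
#' @return `dmi()`: the delay modulation index in [-1, 1].
#' @export
dmi <- function(slopes, direction = c("enhanced", "suppressed")) {
  direction <- match.arg(direction)
  slopes <- slopes[is.finite(slopes)]
  n_pos <- sum(slopes > 0); n_neg <- sum(slopes < 0)
  if (n_pos + n_neg == 0) return(NA_real_)
  val <- (n_pos - n_neg) / (n_pos + n_neg)
  if (direction == "suppressed") -val else val
}
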