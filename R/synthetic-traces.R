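#' Response archetype names
#'
#' The six response classes used by the generator and recovered by the
#' clustering stage: four enhanced (stimulus-driven, stimulus+response,
#' delay-driven, response-driven) and two suppressed (delay-sensitive early
#' and late suppression).
#' @export
archetype_names <- function() {
  c("StimOnly", "StimResp", "Delay", "RespOnly",
    "SuppDelayEarly", "SuppDelayLate")
}

archetype_sign <- function(name) {
  ifelse(name %in% c("SuppDelayEarly", "SuppDelayLate"), "suppressed",
         "enhanced")
}

#' Default region mixtures over response archetypes
#'
#' Qualitative mixtures for the three cortical regions (V1 rich in
#' stimulus-driven and early-suppressed cells; frontal motor cortex rich in
#' delay-, response-driven and late-suppressed cells; parietal cortex
#' intermediate). These are package defaults for simulation, not measured
#' proportions.
#'
#' @param region one of "V1", "PPC", "fMC".
#' @return named numeric vector over [archetype_names()], summing to 1.
#' @export
region_mixture <- function(region = c("V1", "PPC", "fMC")) {
  region <- match.arg(region)
  m <- switch(region,
    V1  = c(0.35, 0.15, 0.05, 0.08, 0.27, 0.10),
    PPC = c(0.15, 0.22, 0.13, 0.15, 0.15, 0.20),
    fMC = c(0.05, 0.15, 0.25, 0.20, 0.10, 0.25))
  setNames(m, archetype_names())
}

#' Archetype response kernel
#'
#' Noiseless time course of one response archetype for a given delay
#' duration: a piecewise epoch drive (stimulus / delay / response support)
#' convolved with a causal exponential emulating slow indicator decay
#' (half-decay time > 1 s, GCaMP6s-like), normalized to peak magnitude 1.
#' Suppressed archetypes are nonpositive, enhanced nonnegative; the
#' delay-driven kernel's support grows with the delay duration.
#'
#' @param name archetype, one of [archetype_names()].
#' @param delay delay duration (s).
#' @param time_s sample times (s), t = 0 at stimulus onset; defaults to the
#'   grid for this delay alone.
#' @param stim_dur,resp_dur epoch durations (s).
#' @param decay_half_time indicator half-decay time (s), must exceed 1.
#' @param frame_rate sampling rate (Hz), used when `time_s` is NULL.
#' @return numeric vector over `time_s`, peak magnitude 1 (NA beyond trial
#'   end never appears here; the kernel is defined on the supplied grid).
#' @export
archetype_kernel <- function(name, delay, time_s = NULL, stim_dur = 2,
                             resp_dur = 1.5, decay_half_time = 1.5,
                             frame_rate = 5) {
  name <- match.arg(name, archetype_names())
  if (decay_half_time <= 1)
    stop("`decay_half_time` must exceed 1 s", call. = FALSE)
  if (is.null(time_s))
    time_s <- task_time_grid(delay, stim_dur = stim_dur, resp_dur = resp_dur,
                             frame_rate = frame_rate)
  t_resp_on <- stim_dur + delay
  t_resp_off <- t_resp_on + resp_dur
  in_stim <- time_s >= 0 & time_s < stim_dur
  in_delay <- time_s >= stim_dur & time_s < t_resp_on
  in_resp <- time_s >= t_resp_on & time_s < t_resp_off
  half <- stim_dur + delay / 2
  drive <- switch(name,
    StimOnly = as.numeric(in_stim),
    StimResp = as.numeric(in_stim) + as.numeric(in_resp),
    Delay = 0.4 * as.numeric(in_stim) + as.numeric(in_delay | in_resp),
    RespOnly = as.numeric(in_resp),
    SuppDelayEarly = -as.numeric(in_stim | (in_delay & time_s < half)),
    SuppDelayLate = -as.numeric((in_delay & time_s >= half) | in_resp))
  dt <- if (length(time_s) > 1) time_s[2] - time_s[1] else 1 / frame_rate
  a <- 2^(-dt / decay_half_time)
  y <- as.numeric(filter(drive * (1 - a), a, method = "recursive"))
  pk <- max(abs(y))
  if (pk > 0) y <- y / pk
  y
}

#' Generate trial-aligned dF/F traces from response archetypes
#'
#' Simulates a neuron x trial x time dF/F tensor on the 5 Hz trial-aligned
#' grid. Each neuron is assigned an archetype from `mixture`, a peak dF/F
#' amplitude, a preferred trial type, and a selectivity ratio; its noiseless
#' expectation on a trial is the archetype kernel for that trial's delay,
#' scaled by the amplitude on preferred trials and additionally by the
#' selectivity ratio on non-preferred trials. i.i.d. Gaussian noise is added.
#' Samples after a trial's end (shorter delays on the common grid) are NA.
#'
#' @param table a `trial_table` from [generate_session()].
#' @param mixture named archetype proportions (must sum to 1); see
#'   [region_mixture()].
#' @param n_neurons number of neurons.
#' @param noise_sd additive Gaussian noise sd (dF/F units).
#' @param seed integer seed.
#' @param coding "stimulus": preference follows stimulus identity;
#'   "choice": preference follows the lick response.
#' @param decay_half_time indicator half-decay (s).
#' @param amp_meanlog,amp_sdlog lognormal peak-amplitude parameters.
#' @return list of class `trial_traces`: `dff` (neuron x trial x time),
#'   `raw` (uncorrected tensor; equals `dff` plus shared neuropil-like
#'   fluctuation), `time_s`, `table`, and `ground_truth` (per-neuron
#'   archetype, sign, preferred type, amplitude, selectivity ratio, true
#'   onset latency).
#' @export
generate_traces <- function(table, mixture = region_mixture("V1"),
                            n_neurons = 100, noise_sd = 0.1, seed = 1L,
                            coding = c("stimulus", "choice"),
                            decay_half_time = 1.5,
                            amp_meanlog = log(0.6), amp_sdlog = 0.4) {
  stopifnot(inherits(table, "trial_table"), n_neurons >= 1)
  coding <- match.arg(coding)
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("`mixture` must sum to 1", call. = FALSE)
  if (is.null(names(mixture)) || !all(names(mixture) %in% archetype_names()))
    stop("`mixture` must be named by archetype", call. = FALSE)
  cfg <- attr(table, "config") %||% session_config()
  time_s <- task_time_grid(cfg$delay_set, pre_dur = cfg$pre_dur,
                           stim_dur = cfg$stim_dur, resp_dur = cfg$resp_dur,
                           frame_rate = cfg$frame_rate)
  n_t <- length(time_s)
  n_tr <- nrow(table)
  delays <- sort(unique(table$delay_s))

  with_substream(seed, "traces", {
    arch <- sample(names(mixture), n_neurons, replace = TRUE, prob = mixture)
    sign_lab <- archetype_sign(arch)
    amplitude <- rlnorm(n_neurons, amp_meanlog, amp_sdlog)
    preferred <- sample(c("hit", "CR"), n_neurons, replace = TRUE)
    sel_ratio <- ifelse(sign_lab == "enhanced",
                        rbeta(n_neurons, 1, 4), rbeta(n_neurons, 4, 1.5))

    # kernels per archetype x delay on the common grid
    kern <- array(0, c(length(archetype_names()), length(delays), n_t),
                  dimnames = list(archetype_names(), NULL, NULL))
    for (a in archetype_names()) for (di in seq_along(delays)) {
      kern[a, di, ] <- archetype_kernel(a, delays[di], time_s = time_s,
                                        stim_dur = cfg$stim_dur,
                                        resp_dur = cfg$resp_dur,
                                        decay_half_time = decay_half_time,
                                        frame_rate = cfg$frame_rate)
    }
    lat <- vapply(seq_len(n_neurons), function(i) {
      k <- kern[arch[i], length(delays), ]
      idx <- which(abs(k) > 0.01)
      if (length(idx)) max(time_s[idx[1]], 0) else NA_real_
    }, numeric(1))

    pref_stim <- ifelse(preferred == "hit", "target", "nontarget")
    is_pref <- if (coding == "stimulus") {
      outer(pref_stim, table$stimulus, `==`)
    } else {
      outer(preferred == "hit", table$licked, `==`)
    }
    d_idx <- match(table$delay_s, delays)
    n_valid <- vapply(table$delay_s, n_valid_samples, integer(1),
                      time_s = time_s, stim_dur = cfg$stim_dur,
                      resp_dur = cfg$resp_dur)

    dff <- array(NA_real_, c(n_neurons, n_tr, n_t))
    for (tr in seq_len(n_tr)) {
      nv <- n_valid[tr]
      base <- kern[arch, d_idx[tr], seq_len(nv), drop = FALSE]
      dim(base) <- c(n_neurons, nv)
      scale <- amplitude * ifelse(is_pref[, tr], 1, sel_ratio)
      sig <- base * scale
      if (noise_sd > 0)
        sig <- sig + matrix(rnorm(n_neurons * nv, 0, noise_sd), n_neurons, nv)
      dff[, tr, seq_len(nv)] <- sig
    }
    # uncorrected trace: corrected plus a weak shared neuropil-like component
    raw <- dff
    if (noise_sd > 0) {
      for (tr in seq_len(n_tr)) {
        nv <- n_valid[tr]
        np <- rnorm(nv, 0, noise_sd / 4)
        raw[, tr, seq_len(nv)] <- raw[, tr, seq_len(nv)] +
          matrix(np, n_neurons, nv, byrow = TRUE)
      }
    }
    gt <- data.frame(neuron = seq_len(n_neurons), archetype = arch,
                     sign = sign_lab, preferred = preferred,
                     amplitude = amplitude, sel_ratio = sel_ratio,
                     latency_true = lat, stringsAsFactors = FALSE)
    structure(list(dff = dff, raw = raw, time_s = time_s, table = table,
                   ground_truth = gt),
              class = "trial_traces")
  })
}
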