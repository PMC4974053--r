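#' Session configuration for the memory-guided go/no-go task
#'
#' Describes the trial structure used throughout the package: a 2 s drifting
#' grating (target or non-target), a randomly interleaved 0/3/6 s delay, and a
#' 1.5 s response window during which the lick spout is in reach. Hit and
#' false-alarm probabilities may be given per delay to emulate the slight
#' performance decline at longer delays.
#'
#' @param n_trials number of trials.
#' @param delay_set delay durations (s), sampled uniformly per trial.
#' @param stim_dur,resp_dur,pre_dur,iti_dur epoch durations (s).
#' @param p_target probability a trial is a target (go) trial.
#' @param hit_rate,fa_rate lick probabilities on target / non-target trials;
#'   scalar or one value per delay in `delay_set`.
#' @param laser_frac fraction of trials with photoinhibition laser on.
#' @param laser_epoch epoch of laser application for laser-on trials.
#' @param laser_hit_rate,laser_fa_rate lick probabilities on laser-on trials
#'   (default: same as laser-off).
#' @param frame_rate imaging stack rate (Hz).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return object of class `session_config`.
#' @export
session_config <- function(n_trials = 300, delay_set = c(0, 3, 6),
                           stim_dur = 2, resp_dur = 1.5, pre_dur = 1,
                           iti_dur = 3, p_target = 0.5,
                           hit_rate = 0.9, fa_rate = 0.2,
                           laser_frac = 0, laser_epoch = "stimulus",
                           laser_hit_rate = NULL, laser_fa_rate = NULL,
                           frame_rate = 5, seed = 1L) {
  if (length(delay_set) < 1 || any(delay_set < 0))
    stop("`delay_set` must be nonempty and nonnegative", call. = FALSE)
  if (frame_rate <= 0) stop("`frame_rate` must be positive", call. = FALSE)
  assert_prob(p_target, "p_target")
  assert_prob(hit_rate, "hit_rate")
  assert_prob(fa_rate, "fa_rate")
  assert_prob(laser_frac, "laser_frac")
  if (!is.null(laser_hit_rate)) assert_prob(laser_hit_rate, "laser_hit_rate")
  if (!is.null(laser_fa_rate)) assert_prob(laser_fa_rate, "laser_fa_rate")
  if (!length(hit_rate) %in% c(1L, length(delay_set)))
    stop("`hit_rate` must be scalar or one value per delay", call. = FALSE)
  if (!length(fa_rate) %in% c(1L, length(delay_set)))
    stop("`fa_rate` must be scalar or one value per delay", call. = FALSE)
  laser_epoch <- match.arg(laser_epoch, c("stimulus", "delay", "response"))
  structure(list(
    n_trials = as.integer(n_trials), delay_set = delay_set,
    stim_dur = stim_dur, resp_dur = resp_dur, pre_dur = pre_dur,
    iti_dur = iti_dur, p_target = p_target,
    hit_rate = hit_rate, fa_rate = fa_rate,
    laser_frac = laser_frac, laser_epoch = laser_epoch,
    laser_hit_rate = laser_hit_rate, laser_fa_rate = laser_fa_rate,
    frame_rate = frame_rate, seed = as.integer(seed)
  ), class = "session_config")
}

#' Generate a behavioral trial table
#'
#' Draws one session of go/no-go trials: stimulus identity, interleaved delay,
#' lick response (per configured hit/false-alarm rates, optionally differing
#' on laser-on trials), the resulting outcome (hit, miss, CR, FA), and epoch
#' boundary times consistent with the configured durations.
#'
#' @param config a [session_config()].
#' @return `data.frame` of class `trial_table` with columns trial, stimulus,
#'   delay_s, licked, outcome, laser_on, laser_epoch, t_stim_on, t_stim_off,
#'   t_spout_in, t_spout_out, and the config stored in attributes.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  cfg <- config
  with_substream(cfg$seed, "session", {
    n <- cfg$n_trials
    stimulus <- ifelse(runif(n) < cfg$p_target, "target", "nontarget")
    delay <- cfg$delay_set[sample.int(length(cfg$delay_set), n, replace = TRUE)]
    d_idx <- match(delay, cfg$delay_set)
    laser_on <- runif(n) < cfg$laser_frac
    hr <- rep(cfg$hit_rate, length.out = length(cfg$delay_set))[d_idx]
    fr <- rep(cfg$fa_rate, length.out = length(cfg$delay_set))[d_idx]
    if (!is.null(cfg$laser_hit_rate))
      hr[laser_on] <- rep(cfg$laser_hit_rate,
                          length.out = length(cfg$delay_set))[d_idx[laser_on]]
    if (!is.null(cfg$laser_fa_rate))
      fr[laser_on] <- rep(cfg$laser_fa_rate,
                          length.out = length(cfg$delay_set))[d_idx[laser_on]]
    p_lick <- ifelse(stimulus == "target", hr, fr)
    licked <- runif(n) < p_lick
    outcome <- ifelse(stimulus == "target",
                      ifelse(licked, "hit", "miss"),
                      ifelse(licked, "FA", "CR"))
    tab <- data.frame(
      trial = seq_len(n),
      stimulus = stimulus,
      delay_s = delay,
      licked = licked,
      outcome = outcome,
      laser_on = laser_on,
      laser_epoch = ifelse(laser_on, cfg$laser_epoch, "none"),
      t_stim_on = 0,
      t_stim_off = cfg$stim_dur,
      t_spout_in = cfg$stim_dur + delay,
      t_spout_out = cfg$stim_dur + delay + cfg$resp_dur,
      stringsAsFactors = FALSE
    )
    attr(tab, "config") <- cfg
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}

#' Write / read a trial table as CSV
#'
#' @param table a `trial_table`.
#' @param path file path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns a `trial_table`.
#' @export
write_trial_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "stimulus", "delay_s", "licked", "outcome",
            "t_stim_on", "t_stim_off", "t_spout_in", "t_spout_out")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(tab$laser_on)) tab$laser_on <- FALSE
  if (is.null(tab$laser_epoch)) tab$laser_epoch <- "none"
  tab$licked <- as.logical(tab$licked)
  tab$laser_on <- as.logical(tab$laser_on)
  class(tab) <- c("trial_table", "data.frame")
  tab
}
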