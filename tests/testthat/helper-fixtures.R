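# Shared fixture builders. Everything is generated in code at test time.

# A small balanced session: exactly n_per correct trials of each
# (type, delay) stratum, no errors unless asked for.
balanced_table <- function(n_per = 8, delays = c(0, 3, 6), n_miss = 0,
                           n_fa = 0) {
  rows <- list()
  add <- function(stim, licked, outcome, delay, n) {
    if (n == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      stimulus = stim, delay_s = delay, licked = licked, outcome = outcome,
      n = n)
  }
  for (d in delays) {
    add("target", TRUE, "hit", d, n_per)
    add("nontarget", FALSE, "CR", d, n_per)
    add("target", FALSE, "miss", d, n_miss)
    add("nontarget", TRUE, "FA", d, n_fa)
  }
  long <- do.call(rbind, rows)
  long <- long[rep(seq_len(nrow(long)), long$n), ]
  tab <- data.frame(
    trial = seq_len(nrow(long)), stimulus = long$stimulus,
    delay_s = long$delay_s, licked = long$licked, outcome = long$outcome,
    laser_on = FALSE, laser_epoch = "none",
    t_stim_on = 0, t_stim_off = 2,
    t_spout_in = 2 + long$delay_s, t_spout_out = 3.5 + long$delay_s,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(tab, "config") <- session_config(n_trials = nrow(tab),
                                        delay_set = delays)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

# Hand-built trial_traces from an explicit tensor (neuron x trial x time).
make_traces <- function(dff, table, time_s, raw = NULL) {
  structure(list(dff = dff, raw = raw %||% dff, time_s = time_s,
                 table = table, ground_truth = NULL),
            class = "trial_traces")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tensor whose noiseless expectation follows one archetype on every trial.
archetype_tensor <- function(table, archetype, amplitude = 0.8,
                             noise_sd = 0, seed = 1) {
  time_s <- task_time_grid(sort(unique(table$delay_s)))
  n_tr <- nrow(table)
  set.seed(seed)
  dff <- array(NA_real_, c(1, n_tr, length(time_s)))
  for (tr in seq_len(n_tr)) {
    k <- archetype_kernel(archetype, table$delay_s[tr], time_s = time_s)
    nv <- sum(time_s < table$t_spout_out[tr] - 1e-9)
    x <- amplitude * k[seq_len(nv)]
    if (noise_sd > 0) x <- x + rnorm(nv, 0, noise_sd)
    dff[1, tr, seq_len(nv)] <- x
  }
  make_traces(dff, table, time_s)
}

# Exhaustive Mann-Whitney auROC oracle by pair counting.
auroc_oracle <- function(neg, pos) {
  s <- 0
  for (y in pos) for (x in neg) s <- s + (y > x) + 0.5 * (y == x)
  s / (length(neg) * length(pos))
}

# Population tensor with planted linear stimulus/choice coding.
planted_population <- function(n_neurons = 100, n_trials = 60, n_time = 20,
                               a_scale = 1, b_scale = 1, noise_sd = 0.5,
                               p_correct = 0.85, seed = 1) {
  set.seed(seed)
  a <- rnorm(n_neurons); a <- a / sqrt(sum(a^2))
  b <- rnorm(n_neurons); b <- b - sum(a * b) * a; b <- b / sqrt(sum(b^2))
  stim <- rep(c(1, -1), length.out = n_trials)
  lick <- ifelse(runif(n_trials) < p_correct, stim == 1, stim != 1)
  choice <- ifelse(lick, 1, -1)
  outcome <- ifelse(stim == 1, ifelse(lick, "hit", "miss"),
                    ifelse(lick, "FA", "CR"))
  stim_prof <- exp(-((seq_len(n_time) - 5) / 4)^2)
  choice_prof <- exp(-((seq_len(n_time) - 15) / 4)^2)
  dff <- array(rnorm(n_neurons * n_trials * n_time, 0, noise_sd),
               c(n_neurons, n_trials, n_time))
  for (tr in seq_len(n_trials)) for (t in seq_len(n_time)) {
    dff[, tr, t] <- dff[, tr, t] +
      a_scale * stim[tr] * stim_prof[t] * a +
      b_scale * choice[tr] * choice_prof[t] * b
  }
  list(dff = dff, stimulus = stim, choice = choice, outcome = outcome,
       a = a, b = b)
}
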