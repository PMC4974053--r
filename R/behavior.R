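#' Signal-detection sensitivity (d-prime)
#'
#' d' = qnorm(R_HIT) - qnorm(R_FA), with rates of exactly 0 or 1 clipped to
#' 1/(2N) and 1 - 1/(2N) of the relevant trial count (log-linear correction)
#' so the result is always finite. Used instead of percent correct because it
#' separates sensitivity from lick bias.
#'
#' @param r_hit,r_fa hit and false-alarm rates in [0, 1].
#' @param n_go,n_nogo numbers of go / no-go trials behind the rates.
#' @return d-prime (z-units).
#' @export
compute_d_prime <- function(r_hit, r_fa, n_go, n_nogo) {
  assert_prob(r_hit, "r_hit"); assert_prob(r_fa, "r_fa")
  if (any(c(n_go, n_nogo) < 1)) stop("trial counts must be >= 1",
                                     call. = FALSE)
  clip <- function(r, n) pmin(pmax(r, 1 / (2 * n)), 1 - 1 / (2 * n))
  qnorm(clip(r_hit, n_go)) - qnorm(clip(r_fa, n_nogo))
}

#' Summarize behavioral performance of a session
#'
#' Per-delay and overall contingency counts (hit/miss/CR/FA), hit and
#' false-alarm rates, and d-prime. By default laser-on trials are excluded
#' when any exist, so performance reflects the unperturbed condition.
#'
#' @param table a `trial_table`.
#' @param laser_off_only drop laser-on trials first (default TRUE).
#' @return object of class `session_summary`: data.frame `per_delay`
#'   (delay_s, n_go, n_nogo, n_hit, n_fa, r_hit, r_fa, d_prime) plus
#'   `overall` row.
#' @export
summarize_session <- function(table, laser_off_only = TRUE) {
  stopifnot(inherits(table, "data.frame"))
  if (laser_off_only && any(table$laser_on)) table <- table[!table$laser_on, ]
  one <- function(sub, delay) {
    go <- sub$stimulus == "target"
    n_go <- sum(go); n_nogo <- sum(!go)
    if (n_go == 0 || n_nogo == 0) return(NULL)
    r_hit <- mean(sub$licked[go]); r_fa <- mean(sub$licked[!go])
    data.frame(delay_s = delay, n_go = n_go, n_nogo = n_nogo,
               n_hit = sum(sub$licked[go]), n_fa = sum(sub$licked[!go]),
               r_hit = r_hit, r_fa = r_fa,
               d_prime = compute_d_prime(r_hit, r_fa, n_go, n_nogo))
  }
  delays <- sort(unique(table$delay_s))
  rows <- list()
  for (d in delays) {
    r <- one(table[table$delay_s == d, ], d)
    if (is.null(r)) {
      warning("delay stratum ", d, " s has no go or no-go trials; omitted")
    } else rows[[length(rows) + 1L]] <- r
  }
  per_delay <- do.call(rbind, rows)
  overall <- one(table, NA_real_)
  if (is.null(overall)) stop("session needs >= 1 go and >= 1 no-go trial",
                             call. = FALSE)
  structure(list(per_delay = per_delay, overall = overall),
            class = "session_summary")
}

#' Session inclusion criterion
#'
#' A session passes quality control iff d' > 1 and R_HIT - R_FA > 0.30
#' (both strict), evaluated on the overall laser-off summary.
#'
#' @param summary a `session_summary` or a `trial_table`.
#' @param min_dprime,min_rate_diff thresholds.
#' @return logical pass/fail.
#' @export
session_qc <- function(summary, min_dprime = 1, min_rate_diff = 0.30) {
  if (inherits(summary, "data.frame")) summary <- summarize_session(summary)
  ov <- summary$overall
  (ov$d_prime > min_dprime) && ((ov$r_hit - ov$r_fa) > min_rate_diff)
}

#' Compare laser-ON vs laser-OFF behavior across sessions
#'
#' For a family of photoinhibition sessions with interleaved laser trials
#' applied during one task epoch: computes per-session paired d' (and hit /
#' false-alarm rates) for laser-OFF vs laser-ON trials, a two-sided paired
#' t-test on each measure, and Bonferroni correction across the comparison
#' family (by default the three task epochs).
#'
#' @param sessions list of `trial_table`s.
#' @param epoch laser epoch to test ("stimulus", "delay", "response").
#' @param n_comparisons size of the Bonferroni family (default 3 epochs).
#' @param alpha nominal significance level.
#' @return object of class `laser_comparison` with `pairs` (per-session OFF /
#'   ON values for d_prime, r_hit, r_fa), `tests` (measure, mean_delta,
#'   p_value, p_bonferroni, significant), `alpha_corrected`.
#' @export
compare_laser_conditions <- function(sessions, epoch = "stimulus",
                                     n_comparisons = 3, alpha = 0.05) {
  epoch <- match.arg(epoch, c("stimulus", "delay", "response"))
  if (length(sessions) < 2) stop("need >= 2 sessions", call. = FALSE)
  one_cond <- function(tab) {
    go <- tab$stimulus == "target"
    if (sum(go) == 0 || sum(!go) == 0) return(NULL)
    r_hit <- mean(tab$licked[go]); r_fa <- mean(tab$licked[!go])
    c(d_prime = compute_d_prime(r_hit, r_fa, sum(go), sum(!go)),
      r_hit = r_hit, r_fa = r_fa)
  }
  rows <- list()
  for (i in seq_along(sessions)) {
    tab <- sessions[[i]]
    off <- one_cond(tab[!tab$laser_on, ])
    on <- one_cond(tab[tab$laser_on & tab$laser_epoch == epoch, ])
    if (is.null(off) || is.null(on)) {
      warning("session ", i, " lacks a laser condition; excluded")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      session = i, d_prime_off = off["d_prime"], d_prime_on = on["d_prime"],
      r_hit_off = off["r_hit"], r_hit_on = on["r_hit"],
      r_fa_off = off["r_fa"], r_fa_on = on["r_fa"], row.names = NULL)
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 2)
    stop("fewer than 2 usable sessions", call. = FALSE)
  alpha_c <- alpha / n_comparisons
  test_one <- function(off, on, name) {
    tt <- t.test(on, off, paired = TRUE)
    data.frame(measure = name, mean_delta = mean(on - off),
               p_value = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_comparisons),
               significant = tt$p.value < alpha_c)
  }
  tests <- rbind(
    test_one(pairs$d_prime_off, pairs$d_prime_on, "d_prime"),
    test_one(pairs$r_hit_off, pairs$r_hit_on, "r_hit"),
    test_one(pairs$r_fa_off, pairs$r_fa_on, "r_fa"))
  structure(list(pairs = pairs, tests = tests, epoch = epoch,
                 alpha_corrected = alpha_c),
            class = "laser_comparison")
}
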