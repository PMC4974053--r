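# Exact two-sided signed-rank p-values for many rows at once.
#
# D: matrix (rows = tests, cols = paired differences across trials). Rows are
# assumed continuous (no zeros / ties in |D|); rows containing zeros fall back
# to stats::wilcox.test. Returns list(p, v, direction) where direction is the
# sign of the median difference.
signed_rank_rows <- function(D) {
  n <- ncol(D)
  absD <- abs(D)
  r <- matrix(1, nrow(D), n)
  for (j in seq_len(n)) {
    lt <- 0; eq <- 0
    for (l in seq_len(n)) {
      lt <- lt + (absD[, l] < absD[, j])
      eq <- eq + (absD[, l] == absD[, j])
    }
    r[, j] <- lt + (eq + 1) / 2   # midranks; eq includes self
  }
  v <- rowSums(r * (D > 0))
  has_zero <- rowSums(D == 0) > 0
  p <- 2 * pmin(psignrank(v, n), 1 - psignrank(v - 1, n))
  p <- pmin(p, 1)
  if (any(has_zero)) {
    for (i in which(has_zero)) {
      d <- D[i, ]
      p[i] <- tryCatch(
        suppressWarnings(wilcox.test(d, exact = TRUE)$p.value),
        error = function(e) 1)
    }
  }
  med <- apply(D, 1, median)
  list(p = p, v = v, direction = sign(med))
}

#' Trial-locked response significance test
#'
#' Classifies each neuron as significantly task-driven (enhanced or
#' suppressed) using a low per-sample threshold combined with a duration and
#' reliability requirement, designed for a slow indicator whose genuine
#' transients span many samples: for every time sample, delay condition, and
#' correct trial type (hit, CR), the per-trial sample value is compared to
#' that trial's mean pre-stimulus baseline with a two-sided Wilcoxon
#' signed-rank test (p < `alpha`). A (trial type, delay, direction) qualifies
#' when at least `min_samples` samples are significant in the same direction
#' within that delay's trace; a neuron is significant when some trial type
#' and direction qualifies in at least `min_delays` delays — on both the
#' neuropil-corrected and uncorrected tensors when `require_raw` is TRUE.
#' Short-duration artifacts (e.g. licking movement) fail the duration
#' requirement; the chance level of the full criterion is below 1e-9 (see
#' [significance_chance_level()]).
#'
#' @param traces a `trial_traces` object (fields `dff`, `raw`, `time_s`,
#'   `table`).
#' @param alpha per-sample two-sided significance level.
#' @param min_samples minimum same-direction significant samples per delay
#'   trace.
#' @param min_delays minimum number of qualifying delays.
#' @param min_trials minimum correct trials per (type, delay) stratum; leaner
#'   strata are excluded.
#' @param consecutive require the `min_samples` significant samples to be
#'   consecutive rather than merely counted.
#' @param require_raw require the criterion to pass on the uncorrected
#'   tensor as well.
#' @return object of class `significance_result`: data.frame `neurons`
#'   (neuron, significant, direction) and logical array `qualifying`
#'   (neuron x type x delay x direction) from the corrected tensor.
#' @export
test_significance <- function(traces, alpha = 0.05, min_samples = 10,
                              min_delays = 2, min_trials = 5,
                              consecutive = FALSE, require_raw = TRUE) {
  stopifnot(inherits(traces, "trial_traces"))
  tab <- traces$table
  time_s <- traces$time_s
  base_idx <- which(time_s < 0)
  delays <- sort(unique(tab$delay_s))
  types <- c(hit = "hit", CR = "CR")
  n_neur <- dim(traces$dff)[1]

  qual_for <- function(tensor) {
    qual <- array(FALSE, c(n_neur, length(types), length(delays), 2),
                  dimnames = list(NULL, names(types), paste0(delays),
                                  c("enhanced", "suppressed")))
    for (ti in seq_along(types)) for (di in seq_along(delays)) {
      trials <- which(tab$outcome == types[ti] & tab$delay_s == delays[di])
      if (length(trials) < min_trials) next
      nv <- n_valid_samples(time_s, delays[di])
      X <- tensor[, trials, seq_len(nv), drop = FALSE]
      B <- apply(X[, , base_idx, drop = FALSE], c(1, 2), mean)
      test_idx <- seq_len(nv)[-base_idx]
      # rows = neuron x sample, cols = trials
      D <- matrix(0, n_neur * length(test_idx), length(trials))
      for (k in seq_along(trials)) {
        D[, k] <- as.vector(X[, k, test_idx]) - B[, k]
      }
      res <- signed_rank_rows(D)
      sig_pos <- matrix(res$p < alpha & res$direction > 0,
                        n_neur, length(test_idx))
      sig_neg <- matrix(res$p < alpha & res$direction < 0,
                        n_neur, length(test_idx))
      count_fun <- if (consecutive) {
        function(m) apply(m, 1, function(x) {
          r <- true_runs(x); if (nrow(r)) max(r[, 2] - r[, 1] + 1) else 0
        })
      } else rowSums
      qual[, ti, di, 1] <- count_fun(sig_pos) >= min_samples
      qual[, ti, di, 2] <- count_fun(sig_neg) >= min_samples
    }
    qual
  }

  qual <- qual_for(traces$dff)
  pass_of <- function(q) {
    # for each neuron: any (type, direction) with >= min_delays qualifying
    hits <- apply(q, c(1, 2, 4), sum) >= min_delays
    apply(hits, 1, any)
  }
  pass <- pass_of(qual)
  if (require_raw && !is.null(traces$raw)) {
    pass <- pass & pass_of(qual_for(traces$raw))
  }
  direction <- rep(NA_character_, n_neur)
  n_enh <- apply(qual[, , , 1, drop = FALSE], 1, sum)
  n_sup <- apply(qual[, , , 2, drop = FALSE], 1, sum)
  direction[pass] <- ifelse(n_enh[pass] >= n_sup[pass],
                            "enhanced", "suppressed")
  structure(list(
    neurons = data.frame(neuron = seq_len(n_neur), significant = pass,
                         direction = direction, stringsAsFactors = FALSE),
    qualifying = qual, delays = delays),
    class = "significance_result")
}

#' Analytic chance level of the significance criterion
#'
#' Probability that a single null neuron (independent samples, per-sample
#' two-sided level `alpha`) passes the full trial-locked criterion, bounded
#' by the union over the two directions and two trial types of the
#' probability that at least `min_delays` of `n_delays` independent delay
#' traces each contain `min_samples` or more same-direction significant
#' samples (binomial tails, per-direction rate `alpha/2`).
#'
#' @param n_samples samples per delay trace (use the longest trace for a
#'   conservative bound).
#' @param alpha per-sample two-sided level.
#' @param min_samples,min_delays,n_delays criterion parameters.
#' @param n_types,n_directions union-bound multiplicities.
#' @return upper bound on the per-neuron false-positive probability.
#' @export
significance_chance_level <- function(n_samples = 65, alpha = 0.05,
                                      min_samples = 10, min_delays = 2,
                                      n_delays = 3, n_types = 2,
                                      n_directions = 2) {
  q <- pbinom(min_samples - 1, n_samples, alpha / 2, lower.tail = FALSE)
  j <- seq(min_delays, n_delays)
  p_delays <- sum(choose(n_delays, j) * q^j * (1 - q)^(n_delays - j))
  n_types * n_directions * p_delays
}
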