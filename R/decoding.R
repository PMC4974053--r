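#' Area under the ROC from two score samples
#'
#' Rank-based (Mann-Whitney) auROC: the probability that a randomly chosen
#' member of `pos` scores higher than one of `neg`, ties counting one half.
#'
#' @param neg,pos numeric score vectors.
#' @return auROC in [0, 1].
#' @export
auroc <- function(neg, pos) {
  n1 <- length(neg); n2 <- length(pos)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(neg, pos))
  (sum(r[n1 + seq_len(n2)]) - n2 * (n2 + 1) / 2) / (n1 * n2)
}

contrast_pairs <- function(contrast) {
  if (contrast == "stimulus") {
    list(list(correct = "CR", error = "miss"),
         list(correct = "hit", error = "FA"))
  } else {
    list(list(correct = "hit", error = "miss"),
         list(correct = "CR", error = "FA"))
  }
}

# auROC(t) for one contrast pair and one fixed neuron subset.
# dff: neuron x trial x time; returns numeric vector over time.
pair_auroc_curve <- function(dff, outcomes, pair, neurons) {
  ic <- which(outcomes == pair$correct)
  ie <- which(outcomes == pair$error)
  n_time <- dim(dff)[3]
  out <- rep(NA_real_, n_time)
  Xc <- dff[neurons, ic, , drop = FALSE]
  Xe <- dff[neurons, ie, , drop = FALSE]
  for (t in seq_len(n_time)) {
    Mc <- matrix(Xc[, , t], length(neurons), length(ic))
    Me <- matrix(Xe[, , t], length(neurons), length(ie))
    tot <- rowSums(Mc)
    # leave-one-out template for correct-class trials
    d_c <- sqrt(colSums((Mc - (tot - Mc) / (length(ic) - 1))^2))
    tmpl <- tot / length(ic)
    d_e <- sqrt(colSums((Me - tmpl)^2))
    out[t] <- auroc(d_c, d_e)
  }
  out
}

#' Ideal-observer decoding of stimulus identity or behavioral choice
#'
#' Discriminates error from correct trials differing only in the contrasted
#' variable: the stimulus contrast compares trials with different stimulus
#' but the same response (miss vs. CR, and FA vs. hit), the choice contrast
#' trials with the same stimulus but different response (miss vs. hit, and
#' FA vs. CR). At each time point, each correct trial's population vector is
#' scored by its Euclidean distance to the leave-one-out mean of the other
#' correct trials, and each error trial by its distance to the all-correct
#' template; the auROC of the two distance samples is the discriminability.
#' Curves are averaged over `n_iter` random neuron subsets of size
#' `n_neurons` and over the available symmetric contrast pairs.
#'
#' @param dff neuron x trial x time array (NA-free; typically the longest
#'   delay condition only).
#' @param outcomes trial outcome per trial ("hit", "miss", "CR", "FA").
#' @param contrast "stimulus" or "choice".
#' @param n_neurons population size per iteration.
#' @param n_iter number of random subsets averaged.
#' @param min_error_trials minimum error trials per included contrast pair.
#' @param seed integer seed.
#' @param fold report max(a, 1 - a) so performance is >= 0.5.
#' @return object of class `decoding_curve`: `auroc` (mean curve over time),
#'   `auroc_raw` (unfolded), `n_neurons`, `n_iter`, `contrast`.
#' @export
ideal_observer_auroc <- function(dff, outcomes,
                                 contrast = c("stimulus", "choice"),
                                 n_neurons = 10, n_iter = 100,
                                 min_error_trials = 3, seed = 1L,
                                 fold = TRUE) {
  contrast <- match.arg(contrast)
  stopifnot(length(outcomes) == dim(dff)[2])
  if (n_neurons > dim(dff)[1])
    stop("`n_neurons` exceeds the neuron pool", call. = FALSE)
  pairs <- Filter(function(p) {
    sum(outcomes == p$error) >= min_error_trials &&
      sum(outcomes == p$correct) >= max(2, min_error_trials)
  }, contrast_pairs(contrast))
  if (!length(pairs))
    stop("no contrast pair has enough trials (need >= ", min_error_trials,
         " error trials)", call. = FALSE)
  n_time <- dim(dff)[3]
  with_substream(seed, paste0("auroc_", contrast), {
    acc <- matrix(0, n_iter, n_time)
    for (i in seq_len(n_iter)) {
      neurons <- sample.int(dim(dff)[1], n_neurons)
      cur <- rowMeans(vapply(pairs, function(p)
        pair_auroc_curve(dff, outcomes, p, neurons), numeric(n_time)))
      acc[i, ] <- cur
    }
    raw <- colMeans(acc)
    structure(list(auroc = if (fold) pmax(raw, 1 - raw) else raw,
                   auroc_raw = raw, n_neurons = n_neurons, n_iter = n_iter,
                   contrast = contrast),
              class = "decoding_curve")
  })
}

#' Permutation null for decoding curves
#'
#' Recomputes the (folded) auROC curve with trial labels shuffled within
#' each contrast pair, one random neuron subset per permutation, and returns
#' the per-time 95% confidence bound of the null distribution.
#'
#' @inheritParams ideal_observer_auroc
#' @param n_perm number of permutations.
#' @return list of class `decoding_null`: `ci_upper`, `ci_lower` (per-time
#'   2.5/97.5% quantiles of the folded null), `mean` (null mean, unfolded).
#' @export
shuffle_null <- function(dff, outcomes, contrast = c("stimulus", "choice"),
                         n_neurons = 10, n_perm = 200,
                         min_error_trials = 3, seed = 1L) {
  contrast <- match.arg(contrast)
  pairs <- Filter(function(p) {
    sum(outcomes == p$error) >= min_error_trials &&
      sum(outcomes == p$correct) >= max(2, min_error_trials)
  }, contrast_pairs(contrast))
  if (!length(pairs)) stop("no usable contrast pair", call. = FALSE)
  n_time <- dim(dff)[3]
  with_substream(seed, paste0("null_", contrast), {
    acc <- matrix(0, n_perm, n_time)
    for (i in seq_len(n_perm)) {
      neurons <- sample.int(dim(dff)[1], n_neurons)
      perm_out <- outcomes
      for (p in pairs) {
        idx <- which(outcomes %in% c(p$correct, p$error))
        perm_out[idx] <- sample(outcomes[idx])
      }
      cur <- rowMeans(vapply(pairs, function(p)
        pair_auroc_curve(dff, perm_out, p, neurons), numeric(n_time)))
      acc[i, ] <- cur
    }
    fold <- pmax(acc, 1 - acc)
    structure(list(ci_upper = apply(fold, 2, quantile, 0.975),
                   ci_lower = apply(fold, 2, quantile, 0.025),
                   mean = colMeans(acc), n_perm = n_perm),
              class = "decoding_null")
  })
}

#' Significant decoding epochs
#'
#' Maximal runs of at least `min_run` consecutive time points at which the
#' decoding curve exceeds the permutation confidence bound (the run-length
#' requirement compensates for multiple comparisons across time).
#'
#' @param curve decoding curve values (or a `decoding_curve`).
#' @param ci_upper per-time upper confidence bound (or a `decoding_null`).
#' @param time_s sample times (s).
#' @param min_run minimum run length (time points).
#' @return data.frame with columns start_s, end_s (zero rows when none).
#' @export
significance_epochs <- function(curve, ci_upper, time_s, min_run = 3) {
  if (inherits(curve, "decoding_curve")) curve <- curve$auroc
  if (inherits(ci_upper, "decoding_null")) ci_upper <- ci_upper$ci_upper
  stopifnot(length(curve) == length(ci_upper),
            length(curve) == length(time_s))
  runs <- true_runs(curve > ci_upper, min_len = min_run)
  data.frame(start_s = time_s[runs[, 1]], end_s = time_s[runs[, 2]])
}
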