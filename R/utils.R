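#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef cor density dist fft filter hclust
#'   cutree lm median na.omit pbinom prcomp psignrank qnorm quantile
#'   rbinom rlnorm rnorm runif rbeta sd setNames t.test var wilcox.test
#' @importFrom graphics hist
#' @importFrom utils read.csv write.csv combn head tail
NULL

# Derive a reproducible 32-bit substream seed from a master seed and a stream
# label, so adding one generator stream never perturbs another.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, label))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Trial-aligned time grid
#'
#' Sample times (seconds) at the imaging stack rate, with t = 0 at stimulus
#' onset and a 1 s pre-stimulus baseline. The grid always spans the longest
#' delay in `delay_set`; trials with shorter delays end earlier and are
#' NA-padded in trial-aligned tensors.
#'
#' @param delay_set numeric vector of delay durations (s).
#' @param pre_dur,stim_dur,resp_dur epoch durations (s).
#' @param frame_rate imaging stack rate (Hz).
#' @return numeric vector of sample times (s).
#' @export
task_time_grid <- function(delay_set = c(0, 3, 6), pre_dur = 1, stim_dur = 2,
                           resp_dur = 1.5, frame_rate = 5) {
  dt <- 1 / frame_rate
  t_end <- stim_dur + max(delay_set) + resp_dur
  seq(-pre_dur, t_end - dt + 1e-9, by = dt)
}

# Number of valid samples for a trial of the given delay on a grid built with
# the same epoch durations.
n_valid_samples <- function(time_s, delay, stim_dur = 2, resp_dur = 1.5) {
  sum(time_s < stim_dur + delay + resp_dur - 1e-9)
}

# Maximal runs of TRUE of length >= min_len; returns a matrix with columns
# start, end (indices), zero rows when none qualify.
true_runs <- function(x, min_len = 1L) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}

# Pearson correlation between a vector and each column of a matrix.
cor_vec_mat <- function(v, M) {
  suppressWarnings(as.vector(cor(v, M)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
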