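#' Targeted dimensionality reduction: task axes
#'
#' Defines de-mixed, orthonormal stimulus and choice axes in neuron space.
#' Per time point, each neuron's single-trial responses are regressed on the
#' coded stimulus (+1 target / -1 non-target) and choice (+1 lick / -1
#' no-lick); per task variable the per-time coefficient vectors are
#' combined (by default a squared-norm-weighted average over time, which is
#' considerably less noisy than any single time point; the maximal-norm
#' time point is available via `t_select`), projected into the subspace of
#' the first `n_pcs` principal components of the trial-averaged responses
#' (de-noising), and the two vectors are orthogonalized by Gram-Schmidt
#' (stimulus first by default) and normalized.
#'
#' @param dff neuron x trial x time array (NA-free).
#' @param stimulus per-trial stimulus ("target"/"nontarget" or +1/-1).
#' @param choice per-trial choice (logical lick, or +1/-1).
#' @param n_pcs number of principal components for de-noising.
#' @param order orthogonalization order, "stimulus_first" or
#'   "choice_first".
#' @param t_select how per-time coefficients are combined: "weighted"
#'   (squared-norm-weighted average) or "max_norm" (single best time
#'   point).
#' @return object of class `task_axes`: unit, mutually orthogonal `stimulus`
#'   and `choice` vectors (length = neurons), `pc_basis`, peak time
#'   indices `t_stim`, `t_choice`.
#' @export
fit_task_axes <- function(dff, stimulus, choice, n_pcs = 10,
                          order = c("stimulus_first", "choice_first"),
                          t_select = c("weighted", "max_norm")) {
  order <- match.arg(order)
  t_select <- match.arg(t_select)
  n_neur <- dim(dff)[1]; n_trial <- dim(dff)[2]; n_time <- dim(dff)[3]
  stopifnot(length(stimulus) == n_trial, length(choice) == n_trial)
  s_code <- if (is.numeric(stimulus)) stimulus else
    ifelse(stimulus == "target", 1, -1)
  c_code <- if (is.numeric(choice)) choice else ifelse(choice, 1, -1)
  if (abs(suppressWarnings(cor(s_code, c_code))) > 0.999 ||
      !is.finite(suppressWarnings(cor(s_code, c_code))))
    stop("stimulus and choice codes are collinear; include error trials",
         call. = FALSE)
  if (n_neur < n_pcs) n_pcs <- n_neur
  # de-noising basis from trial-averaged responses (conditions x time)
  conds <- unique(paste(s_code, c_code))
  avg <- matrix(0, n_neur, 0)
  for (cn in conds) {
    idx <- which(paste(s_code, c_code) == cn)
    avg <- cbind(avg, apply(dff[, idx, , drop = FALSE], c(1, 3), mean))
  }
  pca <- prcomp(t(avg), center = TRUE, scale. = FALSE)
  P <- pca$rotation[, seq_len(min(n_pcs, ncol(pca$rotation))), drop = FALSE]
  # per-time regression across trials
  Z <- cbind(1, s_code, c_code)
  ZtZi <- solve(crossprod(Z))
  beta_s <- matrix(0, n_neur, n_time)
  beta_c <- matrix(0, n_neur, n_time)
  for (t in seq_len(n_time)) {
    Yt <- t(matrix(dff[, , t], n_neur, n_trial))   # trials x neurons
    B <- ZtZi %*% crossprod(Z, Yt)
    beta_s[, t] <- B[2, ]
    beta_c[, t] <- B[3, ]
  }
  t_stim <- which.max(colSums(beta_s^2))
  t_choice <- which.max(colSums(beta_c^2))
  combine <- function(B, t_peak) {
    if (t_select == "max_norm") return(B[, t_peak])
    w <- colSums(B^2)
    as.vector(B %*% (w / sum(w)))
  }
  denoise <- function(v) as.vector(P %*% crossprod(P, v))
  bs <- denoise(combine(beta_s, t_stim))
  bc <- denoise(combine(beta_c, t_choice))
  gs <- function(first, second) {
    u1 <- first / sqrt(sum(first^2))
    u2 <- second - sum(second * u1) * u1
    u2 <- u2 / sqrt(sum(u2^2))
    list(u1, u2)
  }
  if (order == "stimulus_first") {
    u <- gs(bs, bc); stim_axis <- u[[1]]; choice_axis <- u[[2]]
  } else {
    u <- gs(bc, bs); choice_axis <- u[[1]]; stim_axis <- u[[2]]
  }
  structure(list(stimulus = stim_axis, choice = choice_axis, pc_basis = P,
                 t_stim = t_stim, t_choice = t_choice, order = order),
            class = "task_axes")
}

#' Project population activity onto the task axes
#'
#' Condition-averaged population vectors are projected per time point onto
#' the stimulus and choice axes, giving 2-D state-space trajectories per
#' condition, and the hit-minus-CR separation along each axis. A permutation
#' confidence band is built by shuffling trial condition labels (refitting
#' the axes per permutation by default, since the axes depend on the
#' labels).
#'
#' @param dff neuron x trial x time array.
#' @param outcomes per-trial outcome.
#' @param axes a `task_axes` from [fit_task_axes()].
#' @param stimulus,choice trial codes, as in [fit_task_axes()] (needed when
#'   `refit_axes = TRUE`).
#' @param conditions two outcomes to compare (default hit vs. CR).
#' @param n_perm permutations for the confidence band (0 = none).
#' @param refit_axes refit axes on each permutation.
#' @param seed integer seed.
#' @return object of class `trajectory`: per-condition `coords`
#'   (time x 2, choice/stimulus), `delta_stim`, `delta_choice` (hit - CR per
#'   time), and `ci` (2.5/97.5% quantile bands per axis) when `n_perm > 0`.
#' @export
project_trajectories <- function(dff, outcomes, axes, stimulus = NULL,
                                 choice = NULL,
                                 conditions = c("hit", "CR"), n_perm = 0,
                                 refit_axes = TRUE, seed = 1L) {
  stopifnot(inherits(axes, "task_axes"))
  if (!all(conditions %in% outcomes))
    stop("condition absent from `outcomes`: ",
         paste(setdiff(conditions, outcomes), collapse = ", "),
         call. = FALSE)
  n_time <- dim(dff)[3]
  proj <- function(outc, ax) {
    coords <- lapply(conditions, function(cn) {
      idx <- which(outc == cn)
      M <- apply(dff[, idx, , drop = FALSE], c(1, 3), mean)
      cbind(choice = as.vector(crossprod(M, ax$choice)),
            stimulus = as.vector(crossprod(M, ax$stimulus)))
    })
    names(coords) <- conditions
    coords
  }
  coords <- proj(outcomes, axes)
  delta_stim <- coords[[1]][, "stimulus"] - coords[[2]][, "stimulus"]
  delta_choice <- coords[[1]][, "choice"] - coords[[2]][, "choice"]
  ci <- NULL
  if (n_perm > 0) {
    with_substream(seed, "trajectory_perm", {
      ds <- matrix(0, n_perm, n_time); dc <- matrix(0, n_perm, n_time)
      idx_pool <- which(outcomes %in% conditions)
      for (i in seq_len(n_perm)) {
        perm_out <- outcomes
        perm_out[idx_pool] <- sample(outcomes[idx_pool])
        ax <- axes
        if (refit_axes && !is.null(stimulus) && !is.null(choice)) {
          perm_trials <- match(perm_out[idx_pool], outcomes[idx_pool])
          s2 <- stimulus; c2 <- choice
          s2[idx_pool] <- stimulus[idx_pool][perm_trials]
          c2[idx_pool] <- choice[idx_pool][perm_trials]
          ax <- tryCatch(fit_task_axes(dff, s2, c2,
                                       n_pcs = ncol(axes$pc_basis),
                                       order = axes$order),
                         error = function(e) axes)
        }
        pc <- proj(perm_out, ax)
        ds[i, ] <- pc[[1]][, "stimulus"] - pc[[2]][, "stimulus"]
        dc[i, ] <- pc[[1]][, "choice"] - pc[[2]][, "choice"]
      }
      ci <- list(
        stim_upper = apply(ds, 2, quantile, 0.975),
        stim_lower = apply(ds, 2, quantile, 0.025),
        choice_upper = apply(dc, 2, quantile, 0.975),
        choice_lower = apply(dc, 2, quantile, 0.025))
    })
  }
  structure(list(coords = coords, delta_stim = delta_stim,
                 delta_choice = delta_choice, ci = ci,
                 conditions = conditions),
            class = "trajectory")
}
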