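#' Template difference maps for behavior-video movement analysis
#'
#' Quantifies condition-specific movement from behavior-camera frames using
#' a leave-one-out correct-reject (CR) template. For each frame index f:
#' D_CR = mean over f of |CR_f - mean(CR without f)| (baseline movement),
#' D_Hit = mean over f of |Hit_f - mean(CR without f)|, and the
#' condition-specific movement D_Sub = |D_Hit - D_CR|, all pixel-wise. When
#' there are more Hit than CR frames, the excluded CR frame for the surplus
#' Hit frames is chosen at random (seeded).
#'
#' @param hit_frames,cr_frames height x width x n arrays (>= 2 CR frames).
#' @param seed seed for the random CR exclusion on count mismatch.
#' @return object of class `difference_map`: matrices `D_CR`, `D_Hit`,
#'   `D_Sub`, and scalar pixel means `mean_cr`, `mean_hit`, `mean_sub`.
#' @export
template_difference <- function(hit_frames, cr_frames, seed = 1L) {
  stopifnot(length(dim(cr_frames)) == 3, length(dim(hit_frames)) == 3)
  n_cr <- dim(cr_frames)[3]; n_hit <- dim(hit_frames)[3]
  if (n_cr < 2) stop("need >= 2 CR frames for the template", call. = FALSE)
  cr_sum <- apply(cr_frames, c(1, 2), sum)
  loo <- function(f) (cr_sum - cr_frames[, , f]) / (n_cr - 1)
  D_CR <- 0
  for (f in seq_len(n_cr)) D_CR <- D_CR + abs(cr_frames[, , f] - loo(f))
  D_CR <- D_CR / n_cr
  excl <- with_substream(seed, "movement_excl", {
    e <- seq_len(n_hit)
    over <- e > n_cr
    e[over] <- sample.int(n_cr, sum(over), replace = TRUE)
    e
  })
  D_Hit <- 0
  for (f in seq_len(n_hit))
    D_Hit <- D_Hit + abs(hit_frames[, , f] - loo(excl[f]))
  D_Hit <- D_Hit / n_hit
  D_Sub <- abs(D_Hit - D_CR)
  structure(list(D_CR = D_CR, D_Hit = D_Hit, D_Sub = D_Sub,
                 mean_cr = mean(D_CR), mean_hit = mean(D_Hit),
                 mean_sub = mean(D_Sub)),
            class = "difference_map")
}

#' Per-epoch movement maps for one session
#'
#' Applies [template_difference()] to each task epoch of a `frame_set`.
#'
#' @param frame_set output of [generate_video_frames()] (or a list with
#'   `frames$Hit[[epoch]]` / `frames$CR[[epoch]]`).
#' @param seed passed to [template_difference()].
#' @return named list of `difference_map` per epoch.
#' @export
movement_maps <- function(frame_set, seed = 1L) {
  epochs <- names(frame_set$frames$CR)
  maps <- lapply(epochs, function(ep)
    template_difference(frame_set$frames$Hit[[ep]],
                        frame_set$frames$CR[[ep]], seed = seed))
  names(maps) <- epochs
  maps
}

#' Compare movement between task epochs across sessions
#'
#' Paired t-tests of the mean subtracted difference map (mean D_Sub) between
#' epoch pairs (Pre vs Delay, Pre vs Response, Delay vs Response) across
#' sessions, Bonferroni-corrected over the three comparisons. With fewer
#' than 3 sessions only descriptive summaries are returned.
#'
#' @param session_maps list (one element per session) of per-epoch
#'   `difference_map` lists (see [movement_maps()]).
#' @param alpha nominal level.
#' @return object of class `movement_test`: `means` (session x epoch matrix
#'   of mean D_Sub), `tests` (pair, mean_diff, p_value, p_bonferroni,
#'   significant) or NULL when descriptive only.
#' @export
epoch_movement_test <- function(session_maps, alpha = 0.05) {
  epochs <- names(session_maps[[1]])
  means <- t(vapply(session_maps,
                    function(m) vapply(m, function(d) d$mean_sub,
                                       numeric(1)),
                    numeric(length(epochs))))
  colnames(means) <- epochs
  tests <- NULL
  if (nrow(means) >= 3) {
    prs <- utils::combn(epochs, 2, simplify = FALSE)
    rows <- lapply(prs, function(p) {
      tt <- t.test(means[, p[1]], means[, p[2]], paired = TRUE)
      data.frame(pair = paste(p, collapse = " vs "),
                 mean_diff = mean(means[, p[2]] - means[, p[1]]),
                 p_value = tt$p.value,
                 p_bonferroni = min(1, tt$p.value * length(prs)),
                 significant = tt$p.value < alpha / length(prs))
    })
    tests <- do.call(rbind, rows)
  } else {
    warning("fewer than 3 sessions: descriptive output only")
  }
  structure(list(means = means, tests = tests), class = "movement_test")
}
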