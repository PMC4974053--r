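test_that("auROC equals exhaustive pair counting", {
  expect_equal(auroc(c(0.1, 0.2), c(0.3, 0.4)), 1.0)
  expect_equal(auroc(c(0.1, 0.3), c(0.2, 0.4)), 0.75)
  set.seed(77)
  for (i in 1:60) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    neg <- round(rnorm(n1), 1); pos <- round(rnorm(n2), 1)  # force ties
    expect_equal(auroc(neg, pos), auroc_oracle(neg, pos), tolerance = 1e-12)
  }
})

test_that("stimulus and choice decoding doubly dissociate", {
  tab <- generate_session(session_config(n_trials = 260, hit_rate = 0.85,
                                         fa_rate = 0.2, seed = 41))
  keep <- tab$delay_s == 6
  nv <- sum(task_time_grid(c(0, 3, 6)) < 9.5 - 1e-9)
  run_one <- function(coding) {
    tr <- generate_traces(tab, n_neurons = 120, noise_sd = 0.1, seed = 42,
                          coding = coding)
    dff6 <- tr$dff[, keep, seq_len(nv)]
    out6 <- tab$outcome[keep]
    res <- list()
    for (ctr in c("stimulus", "choice")) {
      cur <- ideal_observer_auroc(dff6, out6, ctr, n_neurons = 50,
                                  n_iter = 15, seed = 2)
      nul <- shuffle_null(dff6, out6, ctr, n_neurons = 50, n_perm = 60,
                          seed = 3)
      res[[ctr]] <- list(curve = cur, null = nul,
                         epochs = significance_epochs(
                           cur, nul, tr$time_s[seq_len(nv)]))
    }
    res
  }
  stim_pop <- run_one("stimulus")
  expect_gt(max(stim_pop$stimulus$curve$auroc), 0.95)
  expect_gt(nrow(stim_pop$stimulus$epochs), 0)
  # choice not encoded: nowhere supra-CI for 3+ consecutive points
  expect_equal(nrow(stim_pop$choice$epochs), 0)
  choice_pop <- run_one("choice")
  expect_gt(nrow(choice_pop$choice$epochs), 0)
  expect_equal(nrow(choice_pop$stimulus$epochs), 0)
})

test_that("shuffle null is centered at chance and reproducible", {
  pop <- planted_population(n_neurons = 30, n_trials = 48, n_time = 10,
                            a_scale = 0, b_scale = 0, seed = 4)
  nul <- shuffle_null(pop$dff, pop$outcome, "stimulus", n_neurons = 10,
                      n_perm = 100, seed = 5)
  expect_true(all(abs(nul$mean - 0.5) < 0.1))
  nul2 <- shuffle_null(pop$dff, pop$outcome, "stimulus", n_neurons = 10,
                       n_perm = 100, seed = 5)
  expect_identical(nul$ci_upper, nul2$ci_upper)
  expect_true(all(nul$ci_upper >= 0.5))
})

test_that("null confidence bound narrows with trial count", {
  width_at <- function(n_trials) {
    pop <- planted_population(n_neurons = 20, n_trials = n_trials,
                              n_time = 6, a_scale = 0, b_scale = 0,
                              p_correct = 0.75, seed = 6)
    nul <- shuffle_null(pop$dff, pop$outcome, "stimulus", n_neurons = 10,
                        n_perm = 120, seed = 7)
    mean(nul$ci_upper - 0.5)
  }
  expect_gt(width_at(48), width_at(192))
})

test_that("significant epochs respect the three-point run rule", {
  time_s <- seq(0, 1.8, by = 0.2)
  ci <- rep(0.6, 10)
  expect_equal(nrow(significance_epochs(rep(0.55, 10), ci, time_s)), 0)
  two <- rep(0.5, 10); two[4:5] <- 0.7
  expect_equal(nrow(significance_epochs(two, ci, time_s)), 0)
  five <- rep(0.5, 10); five[5:9] <- 0.7
  ep <- significance_epochs(five, ci, time_s)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start_s, time_s[5])
  expect_equal(ep$end_s, time_s[9])
})

test_that("decoding errors on inadequate inputs", {
  pop <- planted_population(n_neurons = 10, n_trials = 30, n_time = 4,
                            seed = 8)
  expect_error(ideal_observer_auroc(pop$dff, pop$outcome, "stimulus",
                                    n_neurons = 99), "pool")
  only_correct <- ifelse(pop$stimulus == 1, "hit", "CR")
  expect_error(ideal_observer_auroc(pop$dff, only_correct, "stimulus",
                                    n_neurons = 5), "contrast pair")
})

test_that("task axes are orthonormal and recover planted coding directions", {
  pop <- planted_population(n_neurons = 100, n_trials = 160, n_time = 20,
                            a_scale = 1, b_scale = 1, noise_sd = 0.5,
                            seed = 9)
  ax <- fit_task_axes(pop$dff, pop$stimulus, pop$choice)
  expect_equal(sum(ax$stimulus^2), 1, tolerance = 1e-10)
  expect_equal(sum(ax$choice^2), 1, tolerance = 1e-10)
  expect_lt(abs(sum(ax$stimulus * ax$choice)), 1e-10)
  expect_gte(abs(sum(ax$stimulus * pop$a)), 0.95)
  expect_gte(abs(sum(ax$choice * pop$b)), 0.95)
  # flipping the condition codes flips the axis sign only
  ax_fl <- fit_task_axes(pop$dff, -pop$stimulus, pop$choice)
  expect_equal(abs(sum(ax_fl$stimulus * ax$stimulus)), 1, tolerance = 1e-6)
  # no error trials -> collinear codes
  expect_error(fit_task_axes(pop$dff, pop$stimulus, pop$stimulus),
               "collinear")
})

test_that("stimulus-only populations project onto the stimulus axis alone", {
  pop <- planted_population(n_neurons = 100, n_trials = 80, n_time = 20,
                            a_scale = 1.2, b_scale = 0, noise_sd = 0.4,
                            seed = 10)
  ax <- fit_task_axes(pop$dff, pop$stimulus, pop$choice)
  tj <- project_trajectories(pop$dff, pop$outcome, ax, pop$stimulus,
                             pop$choice, n_perm = 60, seed = 11)
  supra_s <- tj$delta_stim > tj$ci$stim_upper |
    tj$delta_stim < tj$ci$stim_lower
  supra_c <- tj$delta_choice > tj$ci$choice_upper |
    tj$delta_choice < tj$ci$choice_lower
  longest_run <- function(x) {
    r <- rle(x); m <- r$lengths[r$values]; if (length(m)) max(m) else 0
  }
  # stimulus separation sustained; choice separation never sustained
  expect_gte(longest_run(supra_s), 3)
  expect_lt(longest_run(supra_c), 3)
})

test_that("trajectory geometry is basis and condition consistent", {
  pop <- planted_population(n_neurons = 60, n_trials = 60, n_time = 12,
                            seed = 12)
  ax <- fit_task_axes(pop$dff, pop$stimulus, pop$choice)
  # identical conditions: zero separation
  tj_same <- project_trajectories(pop$dff, pop$outcome, ax,
                                  conditions = c("hit", "hit"))
  expect_true(all(tj_same$delta_stim == 0))
  expect_true(all(tj_same$delta_choice == 0))
  # orthonormal invariance: swapping orthogonalization order preserves the
  # Euclidean norm of the 2-D separation
  tj <- project_trajectories(pop$dff, pop$outcome, ax)
  ax2 <- fit_task_axes(pop$dff, pop$stimulus, pop$choice,
                       order = "choice_first")
  tj2 <- project_trajectories(pop$dff, pop$outcome, ax2)
  n1 <- sqrt(tj$delta_stim^2 + tj$delta_choice^2)
  n2 <- sqrt(tj2$delta_stim^2 + tj2$delta_choice^2)
  expect_equal(n1, n2, tolerance = 0.15)
  expect_error(project_trajectories(pop$dff, pop$outcome, ax,
                                    conditions = c("hit", "nope")),
               "absent")
})
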