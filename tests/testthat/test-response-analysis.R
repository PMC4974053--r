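test_that("vectorized signed-rank matches wilcox.test on continuous data", {
  set.seed(5)
  for (k in c(6, 8, 12)) {
    D <- matrix(rnorm(40 * k, 0.2), 40, k)
    res <- mgtask:::signed_rank_rows(D)
    p_ref <- apply(D, 1, function(d) wilcox.test(d, exact = TRUE)$p.value)
    expect_equal(res$p, unname(p_ref), tolerance = 1e-12)
  }
})

test_that("noiseless archetype responses are classified with full delay support", {
  tab <- balanced_table(n_per = 7)
  tr <- archetype_tensor(tab, "StimOnly", noise_sd = 0.02, seed = 2)
  sig <- test_significance(tr)
  expect_true(sig$neurons$significant[1])
  expect_equal(sig$neurons$direction[1], "enhanced")
  # all three delays qualify for hit (and CR: unselective tensor)
  expect_equal(sum(sig$qualifying[1, "hit", , "enhanced"]), 3)
  sup <- archetype_tensor(tab, "SuppDelayLate", amplitude = 0.8,
                          noise_sd = 0.02, seed = 3)
  sig_s <- test_significance(sup)
  expect_true(sig_s$neurons$significant[1])
  expect_equal(sig_s$neurons$direction[1], "suppressed")
})

test_that("null neurons essentially never pass the criterion", {
  tab <- balanced_table(n_per = 8)
  time_s <- task_time_grid(c(0, 3, 6))
  set.seed(99)
  n_neur <- 500
  dff <- array(rnorm(n_neur * nrow(tab) * length(time_s), 0, 0.3),
               c(n_neur, nrow(tab), length(time_s)))
  for (tr_i in seq_len(nrow(tab))) {
    nv <- sum(time_s < tab$t_spout_out[tr_i] - 1e-9)
    if (nv < length(time_s)) dff[, tr_i, (nv + 1):length(time_s)] <- NA
  }
  traces <- make_traces(dff, tab, time_s)
  sig <- test_significance(traces, require_raw = FALSE)
  expect_equal(sum(sig$neurons$significant), 0)
})

test_that("analytic chance level is below the 1e-9 bound", {
  p65 <- significance_chance_level(n_samples = 65)
  expect_lt(p65, 1e-9)
  expect_lt(significance_chance_level(n_samples = 52), p65)
  # independent recomputation of the union bound
  q <- pbinom(9, 65, 0.025, lower.tail = FALSE)
  expect_equal(p65, 4 * (3 * q^2 * (1 - q) + q^3), tolerance = 1e-15)
})

test_that("normalization fixes peak magnitude at one", {
  time_s <- task_time_grid(6)
  n_t <- length(time_s)
  enh <- 0.8 * archetype_kernel("StimOnly", 6, time_s = time_s) + 0.1
  sup <- -0.4 * abs(archetype_kernel("SuppDelayLate", 6,
                                     time_s = time_s)) + 0.05
  avg <- rbind(enh, sup)
  attr(avg, "time_s") <- time_s
  norm <- normalize_response(avg, c("enhanced", "suppressed"))
  expect_equal(max(norm[1, ]), 1, tolerance = 1e-12)
  expect_equal(min(norm[2, ]), -1, tolerance = 1e-12)
  # pure offset trace has zero normalizer and is dropped
  avg3 <- rbind(avg, 0.5)
  attr(avg3, "time_s") <- time_s
  expect_warning(out <- normalize_response(avg3,
                                           c("enhanced", "suppressed",
                                             "enhanced")),
                 "dropped")
  expect_equal(nrow(out), 2)
})

test_that("archetype clustering recovers ground-truth classes", {
  tab <- generate_session(session_config(n_trials = 180, seed = 31))
  mix <- setNames(rep(1 / 6, 6), archetype_names())
  tr <- generate_traces(tab, mixture = mix, n_neurons = 300,
                        noise_sd = 0.05, seed = 32)
  avg6 <- trial_average(tr, delay = 6)
  feats <- normalize_response(avg6, tr$ground_truth$sign)
  kept <- as.integer(rownames(feats))
  cm <- cluster_responses(feats, k = 6)
  expect_gte(label_agreement(cm$labels, tr$ground_truth$archetype[kept]),
             0.9)
  expect_equal(choose_k(feats, 1:9), 6)
  # stored correlation is the max over cluster means
  C <- suppressWarnings(cor(t(feats), t(cm$means)))
  expect_equal(cm$correlation, C[cbind(seq_len(nrow(feats)), cm$labels)])
  expect_equal(unname(apply(C, 1, which.max)), unname(cm$labels))
})

test_that("clustering degenerate cases behave", {
  time_s <- task_time_grid(6)
  k1 <- archetype_kernel("StimOnly", 6, time_s = time_s)
  k2 <- archetype_kernel("RespOnly", 6, time_s = time_s)
  feats <- rbind(k1, k1, k2, k2 + 0.01, k1 + 0.005, k2)
  cm <- cluster_responses(feats, k = 2)
  expect_equal(cm$labels[1], cm$labels[2])     # duplicated neuron
  cm1 <- cluster_responses(feats, k = 1)
  expect_true(all(cm1$labels == 1))
  expect_equal(cm1$means[1, ], unname(colMeans(feats)))
  expect_error(cluster_responses(feats, k = 10), "exceeds")
  # two archetypes -> K = 2; identical neurons -> K = 1
  expect_equal(choose_k(feats, 1:4), 2)
  same <- feats[c(1, 1, 1, 1), ]
  expect_equal(choose_k(same, 1:3), 1)
})

test_that("selectivity index follows its defining arithmetic", {
  tab <- balanced_table(n_per = 4, delays = 6)
  time_s <- task_time_grid(6)
  k <- archetype_kernel("StimOnly", 6, time_s = time_s)
  mk_neuron <- function(amp_hit, amp_cr) {
    dff <- array(NA_real_, c(1, nrow(tab), length(time_s)))
    for (i in seq_len(nrow(tab))) {
      amp <- if (tab$outcome[i] == "hit") amp_hit else amp_cr
      dff[1, i, ] <- amp * k
    }
    make_traces(dff, tab, time_s)
  }
  sel1 <- compute_selectivity(mk_neuron(0.3, 0))
  expect_equal(sel1$si, 1)
  expect_equal(sel1$preferred, "hit")
  sel2 <- compute_selectivity(mk_neuron(0.3, 0.3))
  expect_equal(sel2$si, 0, tolerance = 1e-12)
  sel3 <- compute_selectivity(mk_neuron(0.3, 0.1))
  expect_equal(sel3$si, 0.5, tolerance = 1e-12)
  # scale invariance
  sel4 <- compute_selectivity(mk_neuron(3, 1))
  expect_equal(sel4$si, sel3$si, tolerance = 1e-12)
})

test_that("orientation selectivity index arithmetic", {
  expect_equal(compute_osi(c(2, 0), c(0, 90))$osi, 1)
  expect_equal(compute_osi(c(1, 1), c(0, 90))$osi, 0)
  expect_equal(compute_osi(c(2, 1), c(0, 90))$osi, 1 / 3)
  r <- compute_osi(c(0.5, 2, 0.6, 1), c(0, 45, 90, 135))
  expect_equal(r$theta_pref_deg, 45)
  expect_equal(r$r_orth, 1)   # 135 degrees
})

test_that("latency detection uses the sustained threshold-crossing rule", {
  # trace already at the 1000 Hz resolution: upsampling is the identity and
  # the threshold crossing is exact
  time_hi <- round(seq(-1, 9.4, by = 1e-3), 3)
  mk <- function(on, off, sign = 1) {
    tr <- ifelse(time_hi >= on & time_hi < off, sign, 0)
    tr[1] <- 0.01   # nonzero baseline SD
    tr
  }
  expect_equal(estimate_latency(mk(0.2, 2.2), time_hi), 0.2,
               tolerance = 2e-3)
  # excursion shorter than 1 s never qualifies
  expect_true(is.na(estimate_latency(mk(0.2, 1.0), time_hi)))
  # suppressed excursions are detected from the negative side
  expect_equal(estimate_latency(mk(1.0, 3.0, sign = -1), time_hi), 1.0,
               tolerance = 2e-3)
  # latency shifts exactly with the applied offset
  expect_equal(estimate_latency(mk(0.6, 2.6), time_hi) -
                 estimate_latency(mk(0.2, 2.2), time_hi), 0.4,
               tolerance = 1e-6)
  # at the native 5 Hz grid linear interpolation makes the crossing occur
  # between the last zero sample and the first suprathreshold one
  time_lo <- seq(-1, 9.4, by = 0.2)
  tr5 <- ifelse(time_lo >= 0.2 & time_lo < 2.4, 1, 0); tr5[1] <- 0.01
  lat5 <- estimate_latency(tr5, time_lo)
  expect_gte(lat5, 0); expect_lte(lat5, 0.2)
})

test_that("population modal latency finds the first density mode", {
  set.seed(21)
  lat <- c(rnorm(150, 0.1, 0.02), rnorm(100, 1.0, 0.1))
  m <- population_modal_latency(lat)
  expect_equal(m, 0.1, tolerance = 0.05)
  # skewed unimodal: mode near the bulk, not the tail
  lat2 <- c(rnorm(200, 0.3, 0.05), runif(40, 1, 5))
  expect_equal(population_modal_latency(lat2), 0.3, tolerance = 0.1)
})

test_that("delay modulation slopes and DMI", {
  tab <- balanced_table(n_per = 4)
  tr <- archetype_tensor(tab, "Delay", noise_sd = 0)
  dm <- delay_modulation(tr)
  expect_gt(dm$slope[1], 0)
  # DMI arithmetic
  expect_equal(dmi(rep(1, 10), "enhanced"), 1)
  expect_equal(dmi(c(1, 1, 1, -1), "enhanced"), 0.5)
  expect_equal(dmi(rep(-1, 5), "suppressed"), 1)
  expect_equal(dmi(c(1, -1, 0, 0), "enhanced"), 0)  # zeros excluded
  expect_true(is.na(dmi(c(0, 0), "enhanced")))
})
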