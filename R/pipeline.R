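#' Default pipeline configuration
#'
#' All stage parameters in one validated list; defaults follow the analysis
#' conventions used throughout the package (per-sample alpha 0.05, >= 10
#' significant samples in >= 2 of 3 delays, K = 6 response types on 20 PCs,
#' neuropil coefficient 0.7, duplicate thresholds r > 0.5 and 12.5 um,
#' decoding population sizes 1/5/10/50/100). Simulation sizes are kept at
#' desk scale.
#'
#' @param ... named overrides of any default.
#' @return list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_trials = 300, delay_set = c(0, 3, 6), p_target = 0.5,
    hit_rate = 0.9, fa_rate = 0.2,
    n_neurons = 200, noise_sd = 0.1, region = "V1",
    alpha = 0.05, min_samples = 10, min_delays = 2, min_trials = 5,
    k = 6, n_pcs = 20,
    neuropil_coef = 0.7, dup_r = 0.5, dup_dist_um = 12.5,
    decode_sizes = c(1, 5, 10, 50, 100), decode_iters = 50,
    decode_perms = 100, tdr_pcs = 10,
    run_movie = FALSE, run_movement = TRUE,
    movie_cells = 12, movie_noise_sd = 1,
    video_frames = 8
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(ov)] <- ov
  if (cfg$alpha > 0.1)
    warning("nonstandard per-sample alpha (", cfg$alpha, ")")
  structure(cfg, class = c("run_config", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file of config overrides.
#' @return validated `run_config`.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Seeded end-to-end run: trial-table and trace generation, behavioral
#' summary and quality control, trial-locked significance classification,
#' response normalization and archetype clustering, selectivity / latency /
#' delay-modulation indices, ideal-observer decoding of stimulus and choice
#' with permutation nulls, task-axis trajectories, and behavior-video
#' movement statistics. A fixed seed makes the whole bundle reproducible.
#' When `out_dir` is given, tables are written as CSV, statistics as JSON,
#' and the resolved configuration alongside them.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param seed master integer seed for all stages.
#' @param out_dir optional output directory.
#' @return list of class `run_bundle` with elements `table`, `traces`,
#'   `behavior`, `qc`, `significance`, `clusters`, `selectivity`,
#'   `latency`, `delay_mod`, `decoding`, `trajectory`, `movement`,
#'   `config`, `seed`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  scfg <- session_config(n_trials = cfg$n_trials, delay_set = cfg$delay_set,
                         p_target = cfg$p_target, hit_rate = cfg$hit_rate,
                         fa_rate = cfg$fa_rate,
                         seed = substream_seed(seed, "pl_session"))
  table <- generate_session(scfg)
  traces <- generate_traces(table, mixture = region_mixture(cfg$region),
                            n_neurons = cfg$n_neurons,
                            noise_sd = cfg$noise_sd,
                            seed = substream_seed(seed, "pl_traces"))
  behavior <- summarize_session(table)
  qc <- session_qc(behavior)
  sig <- test_significance(traces, alpha = cfg$alpha,
                           min_samples = cfg$min_samples,
                           min_delays = cfg$min_delays,
                           min_trials = cfg$min_trials)
  sel <- compute_selectivity(traces, sig)
  sig_idx <- which(sig$neurons$significant)
  clusters <- NULL
  cluster_df <- NULL
  if (length(sig_idx) >= cfg$k) {
    avg6 <- trial_average(traces, delay = max(cfg$delay_set))
    sub <- avg6[sig_idx, , drop = FALSE]
    attr(sub, "time_s") <- attr(avg6, "time_s")
    feats <- normalize_response(sub, sig$neurons$direction[sig_idx])
    clusters <- cluster_responses(feats, k = cfg$k, n_pcs = cfg$n_pcs)
    cluster_df <- data.frame(neuron = sig_idx[as.integer(rownames(feats))],
                             cluster = clusters$labels)
  }
  avg_all <- trial_average(traces)
  lat <- vapply(seq_len(nrow(avg_all)), function(i)
    estimate_latency(avg_all[i, ], attr(avg_all, "time_s")), numeric(1))
  dm <- delay_modulation(traces)
  # decoding on the longest-delay trials (NA-free portion of the grid)
  dmax <- max(cfg$delay_set)
  keep <- table$delay_s == dmax
  nv <- n_valid_samples(traces$time_s, dmax)
  dff6 <- traces$dff[, keep, seq_len(nv), drop = FALSE]
  out6 <- table$outcome[keep]
  decoding <- list()
  n_dec <- min(max(cfg$decode_sizes), dim(dff6)[1])
  for (ctr in c("stimulus", "choice")) {
    curve <- tryCatch(
      ideal_observer_auroc(dff6, out6, contrast = ctr, n_neurons = n_dec,
                           n_iter = cfg$decode_iters,
                           seed = substream_seed(seed, paste0("dec_", ctr))),
      error = function(e) NULL)
    nullci <- if (!is.null(curve)) tryCatch(
      shuffle_null(dff6, out6, contrast = ctr, n_neurons = n_dec,
                   n_perm = cfg$decode_perms,
                   seed = substream_seed(seed, paste0("nul_", ctr))),
      error = function(e) NULL) else NULL
    epochs <- if (!is.null(curve) && !is.null(nullci))
      significance_epochs(curve, nullci, traces$time_s[seq_len(nv)])
    else NULL
    decoding[[ctr]] <- list(curve = curve, null = nullci, epochs = epochs)
  }
  trajectory <- tryCatch({
    axes <- fit_task_axes(dff6, table$stimulus[keep], table$licked[keep],
                          n_pcs = cfg$tdr_pcs)
    project_trajectories(dff6, out6, axes, table$stimulus[keep],
                         table$licked[keep], n_perm = 0)
  }, error = function(e) NULL)
  movement <- NULL
  if (cfg$run_movement) {
    fsets <- lapply(1:3, function(s)
      generate_video_frames(n_frames = cfg$video_frames,
                            seed = substream_seed(seed,
                                                  paste0("video", s))))
    movement <- epoch_movement_test(
      lapply(seq_along(fsets), function(s)
        movement_maps(fsets[[s]],
                      seed = substream_seed(seed, paste0("maps", s)))))
  }
  bundle <- structure(list(table = table, traces = traces,
                           behavior = behavior, qc = qc,
                           significance = sig, clusters = clusters,
                           cluster_df = cluster_df,
                           selectivity = sel, latency = lat,
                           delay_mod = dm, decoding = decoding,
                           trajectory = trajectory, movement = movement,
                           config = cfg, seed = seed),
                      class = "run_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_table(bundle$table, file.path(out_dir, "trial_table.csv"))
  neurons <- merge(bundle$significance$neurons, bundle$selectivity,
                   by = "neuron")
  neurons$latency_s <- bundle$latency
  neurons$delay_slope <- bundle$delay_mod$slope
  if (!is.null(bundle$cluster_df)) {
    neurons$cluster <- NA_integer_
    neurons$cluster[bundle$cluster_df$neuron] <- bundle$cluster_df$cluster
  }
  write.csv(neurons, file.path(out_dir, "neurons.csv"), row.names = FALSE)
  stats <- list(
    behavior = list(per_delay = bundle$behavior$per_delay,
                    overall = bundle$behavior$overall, qc_pass = bundle$qc),
    decoding = lapply(bundle$decoding, function(d) list(
      auroc = d$curve$auroc %||% NULL,
      ci_upper = d$null$ci_upper %||% NULL,
      epochs = d$epochs)),
    movement = if (!is.null(bundle$movement)) list(
      means = bundle$movement$means, tests = bundle$movement$tests),
    seed = bundle$seed)
  jsonlite::write_json(stats, file.path(out_dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  jsonlite::write_json(unclass(bundle$config),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
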