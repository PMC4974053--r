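#' Trial-averaged response matrix
#'
#' Average dF/F over a subset of trials (by outcome and delay), returning a
#' neuron x time matrix on the valid portion of the grid for that delay.
#'
#' @param traces a `trial_traces`.
#' @param outcome outcomes to include (default correct trials of both
#'   types).
#' @param delay delay condition (s); NULL pools all delays over the common
#'   valid samples of the shortest included delay.
#' @return neuron x time matrix with attribute `time_s`.
#' @export
trial_average <- function(traces, outcome = c("hit", "CR"), delay = NULL) {
  tab <- traces$table
  keep <- tab$outcome %in% outcome
  if (!is.null(delay)) keep <- keep & tab$delay_s %in% delay
  if (!any(keep)) stop("no trials match the requested subset", call. = FALSE)
  nv <- min(vapply(tab$delay_s[keep], n_valid_samples, integer(1),
                   time_s = traces$time_s))
  M <- apply(traces$dff[, keep, seq_len(nv), drop = FALSE], c(1, 3), mean,
             na.rm = TRUE)
  attr(M, "time_s") <- traces$time_s[seq_len(nv)]
  M
}

#' Normalize trial-averaged responses to unit peak
#'
#' Subtracts each neuron's mean baseline (the 1 s before stimulus onset) and
#' divides by the maximum (enhanced neurons) or the magnitude of the minimum
#' (suppressed neurons) of its trial-averaged trace, so every neuron's peak
#' response magnitude is 1.
#'
#' @param avg neuron x time matrix with `time_s` attribute (see
#'   [trial_average()]).
#' @param direction character vector per neuron, "enhanced" or "suppressed".
#' @return normalized matrix; neurons with a zero normalizer are dropped
#'   with a warning (row names give surviving neuron indices).
#' @export
normalize_response <- function(avg, direction) {
  time_s <- attr(avg, "time_s")
  stopifnot(!is.null(time_s), length(direction) == nrow(avg))
  base <- rowMeans(avg[, time_s < 0, drop = FALSE], na.rm = TRUE)
  M <- sweep(avg, 1, base)
  norm <- ifelse(direction == "suppressed",
                 abs(apply(M, 1, min, na.rm = TRUE)),
                 apply(M, 1, max, na.rm = TRUE))
  bad <- !is.finite(norm) | norm == 0
  if (any(bad)) {
    warning(sum(bad), " neuron(s) dropped: zero peak after baseline ",
            "subtraction")
    M <- M[!bad, , drop = FALSE]
    norm <- norm[!bad]
  }
  out <- sweep(M, 1, norm, "/")
  rownames(out) <- which(!bad)
  attr(out, "time_s") <- time_s
  out
}

#' Cluster normalized response traces into response types
#'
#' De-noises the neuron x time feature matrix by projection onto its first
#' `n_pcs` principal components, builds a Ward linkage (Euclidean metric) in
#' PC space, cuts at `k` clusters, and then iteratively re-categorizes every
#' neuron to the cluster whose mean trace has the highest Pearson
#' correlation with the neuron's own trace, updating means until stable.
#'
#' @param features neuron x time matrix (normalized preferred responses).
#' @param k number of clusters.
#' @param n_pcs number of principal components retained (or fewer if the
#'   matrix is smaller).
#' @param max_iter maximum recategorization rounds.
#' @return object of class `cluster_model`: `labels`, `means` (k x time),
#'   `correlation` (per-neuron correlation to its cluster mean), `linkage`
#'   (hclust), `pca` (prcomp), `k`.
#' @export
cluster_responses <- function(features, k = 6, n_pcs = 20, max_iter = 10) {
  stopifnot(is.matrix(features))
  if (k > nrow(features)) stop("k exceeds number of neurons", call. = FALSE)
  pca <- prcomp(features, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  hc <- hclust(dist(scores), method = "ward.D2")
  labels <- cutree(hc, k = k)
  means <- cluster_means(features, labels, k)
  if (k > 1) {
    for (iter in seq_len(max_iter)) {
      C <- suppressWarnings(cor(t(features), t(means)))
      C[!is.finite(C)] <- -Inf
      new_labels <- max.col(C, ties.method = "first")
      if (all(new_labels == labels)) break
      labels <- new_labels
      means <- cluster_means(features, labels, k, prev = means)
    }
  }
  C <- suppressWarnings(cor(t(features), t(means)))
  C[!is.finite(C)] <- NA
  corr <- C[cbind(seq_len(nrow(features)), labels)]
  structure(list(labels = labels, means = means, correlation = corr,
                 linkage = hc, pca = pca, k = k),
            class = "cluster_model")
}

cluster_means <- function(features, labels, k, prev = NULL) {
  means <- matrix(NA_real_, k, ncol(features))
  for (g in seq_len(k)) {
    idx <- labels == g
    if (any(idx)) {
      means[g, ] <- colMeans(features[idx, , drop = FALSE])
    } else if (!is.null(prev)) {
      means[g, ] <- prev[g, ]
    } else {
      means[g, ] <- 0
    }
  }
  means
}

#' Choose the number of response-type clusters
#'
#' Increases K until further division yields highly overlapping average
#' traces: returns the smallest candidate K such that cutting the tree at
#' K + 1 produces some pair of cluster-mean traces whose Pearson correlation
#' exceeds `overlap_r`. If no candidate triggers the rule, the largest
#' candidate is returned.
#'
#' @param features neuron x time matrix.
#' @param candidates candidate K values (increasing).
#' @param overlap_r mean-trace correlation above which two clusters are
#'   considered redundant.
#' @param n_pcs principal components for the linkage.
#' @return selected K.
#' @export
choose_k <- function(features, candidates = 1:10, overlap_r = 0.9,
                     n_pcs = 20) {
  candidates <- sort(candidates)
  pca <- prcomp(features, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  hc <- hclust(dist(pca$x[, seq_len(n_pcs), drop = FALSE]),
               method = "ward.D2")
  for (k in candidates) {
    k1 <- k + 1
    if (k1 > nrow(features)) return(k)
    labels <- cutree(hc, k = k1)
    means <- cluster_means(features, labels, k1)
    C <- suppressWarnings(cor(t(means)))
    diag(C) <- NA
    # numerically identical means (zero variance) always count as overlap
    same <- as.matrix(dist(means, method = "maximum")) < 1e-10
    diag(same) <- FALSE
    if (any(C > overlap_r, na.rm = TRUE) || any(same)) return(k)
  }
  max(candidates)
}

#' Match cluster labels to ground-truth classes
#'
#' Greedy optimal one-to-one matching of predicted clusters to reference
#' classes by overlap count; returns the achieved label agreement (fraction
#' of neurons whose matched cluster equals their reference class).
#'
#' @param labels integer cluster labels.
#' @param truth reference class labels (any type).
#' @return agreement fraction in [0, 1].
#' @export
label_agreement <- function(labels, truth) {
  stopifnot(length(labels) == length(truth))
  tab <- table(labels, truth)
  agree <- 0
  while (nrow(tab) > 0 && ncol(tab) > 0) {
    ij <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[ij[1], ij[2]]
    tab <- tab[-ij[1], -ij[2], drop = FALSE]
  }
  as.numeric(agree) / length(labels)
}
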