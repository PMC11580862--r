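# Filter evaluation: Gaussian surprisal of the true trajectory under the
# predictive belief, hyperparameter tuning sweeps over virtual-patient
# cohorts, closed-form Wasserstein-2 between Gaussians, and phenotype
# clustering of trajectory collections.

#' Gaussian surprisal (nats)
#'
#' Negative log density of the true state under a Gaussian predictive
#' belief: `0.5 [(x - m)' P^-1 (x - m) + d log 2 pi + log det P]`. Low
#' surprisal means a well-calibrated forecast; unlike a plain distance to
#' the ensemble mean it accounts for the predictive uncertainty.
#'
#' @param belief a [gaussian_belief()].
#' @param x_true numeric vector (same transformed space as the belief).
#' @param jitter diagonal regularization applied before inversion.
#' @return surprisal in nats.
#' @export
gaussian_surprisal <- function(belief, x_true, jitter = 1e-10) {
  d <- length(belief$mean)
  stopifnot(length(x_true) == d)
  P <- belief$cov + diag(jitter, d)
  ch <- tryCatch(chol(P), error = function(e) NULL)
  if (is.null(ch)) stop("predictive covariance singular after jitter")
  z <- forwardsolve(t(ch), x_true - belief$mean)
  0.5 * (sum(z^2) + d * log(2 * pi)) + sum(log(diag(ch)))
}

#' Wasserstein-2 distance between two Gaussians
#'
#' Closed form `W2^2 = |m_a - m_b|^2 +
#' tr(S_a + S_b - 2 (S_b^{1/2} S_a S_b^{1/2})^{1/2})`. Matrix square roots
#' use symmetric eigendecomposition with negative eigenvalues clipped at 0.
#'
#' @param a,b [gaussian_belief()] objects of equal dimension.
#' @return the distance `W2` (not squared).
#' @export
gaussian_wasserstein2 <- function(a, b) {
  stopifnot(length(a$mean) == length(b$mean))
  sb <- sqrtm_psd(b$cov)
  cross <- sqrtm_psd(sb %*% a$cov %*% sb)
  w2sq <- sum((a$mean - b$mean)^2) +
    sum(diag(a$cov)) + sum(diag(b$cov)) - 2 * sum(diag(cross))
  sqrt(max(w2sq, 0))
}

#' Covariance entries implied by filtering spatial fields directly
#'
#' Number of distinct off-diagonal-or-upper entries of the covariance matrix
#' of `K` molecular fields on an `N x M` lattice treated as a flat state
#' vector: `K N M (K N M - 1) / 2`. Quantifies why the filter acts on
#' macrostate summaries instead of raw lattices.
#'
#' @param K number of fields; `N`, `M` lattice dimensions.
#' @return the entry count (numeric, exact integer value).
#' @export
covariance_entry_count <- function(K, N, M) {
  d <- as.numeric(K) * as.numeric(N) * as.numeric(M)
  d * (d - 1) / 2
}

#' Tuning sweep over measurement choices and uncertainty levels
#'
#' For each combination of a single observed component and a measurement
#' variance, simulates `n_patients` virtual patients, runs the full
#' assimilation loop against each, and returns the pointwise median
#' surprisal of the true transformed macrostate under the predictive belief.
#' This mirrors the protocol used to pick the measurement uncertainty: try
#' levels (e.g. 10, 1, 0.1, 0.01) and keep the one with the lowest median
#' surprisal.
#'
#' @param config an [experiment_config()].
#' @param measurements character vector of component names to try.
#' @param r_levels numeric vector of measurement variances to try.
#' @param n_patients patients per setting.
#' @param seed base random seed.
#' @return data frame with columns measurement, R, time, median_surprisal.
#' @export
tuning_sweep <- function(config, measurements, r_levels, n_patients, seed = 1) {
  out <- list()
  for (meas in measurements) {
    for (r in r_levels) {
      cfg <- config
      cfg$measure <- measurement_spec(meas, r, config$measure$times)
      sur <- matrix(0, n_patients, cfg$horizon + 1)
      for (p in seq_len(n_patients)) {
        pat <- make_virtual_patient(cfg, seed = mix_seed(seed, p * 7919))
        res <- run_abmkf(cfg, pat, seed = mix_seed(seed, p * 104729 + 1))
        sur[p, ] <- res$surprisal
      }
      med <- apply(sur, 2, stats::median)
      out[[length(out) + 1L]] <- data.frame(measurement = meas, R = r,
                                            time = 0:cfg$horizon,
                                            median_surprisal = med)
    }
  }
  do.call(rbind, out)
}

#' Adjusted Rand index
#'
#' Agreement between two labelings of the same items, corrected for chance;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# mean silhouette width for a labeling given a distance matrix
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(l) mean(d[i, labels == l]), numeric(1))
    b <- if (length(bs)) min(bs) else NA_real_
    s[i] <- if (is.na(b) || max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Phenotype clustering of macrostate trajectories
#'
#' Flattens each trajectory (time x components) into one long vector,
#' reduces the collection by PCA to `n_components` dimensions, and clusters
#' with k-means (10 seeded restarts), choosing k in `[2, k_max]` by mean
#' silhouette width. Clusters of qualitatively similar trajectories driven
#' by regions of parameter space are read as model phenotypes. For each
#' cluster a per-time Gaussian is fitted and the pairwise Wasserstein-2
#' distance series between cluster Gaussians is computed; a sustained rise
#' in that series marks the time at which phenotypes diverge.
#'
#' @param trajectories list of T x d numeric matrices (equal dimensions).
#' @param n_components PCA dimensions (default 3).
#' @param k_max maximum number of clusters to consider.
#' @param seed random seed for the k-means restarts.
#' @return list with `labels`, `k`, `scores` (PCA coordinates),
#'   `cluster_gaussians` (per cluster, per time), and `wasserstein`
#'   (data frame: time, pair, w2).
#' @export
phenotype_clustering <- function(trajectories, n_components = 3, k_max = 6,
                                 seed = 1) {
  n <- length(trajectories)
  if (n < 2) stop("need at least 2 trajectories")
  dims <- dim(trajectories[[1]])
  flat <- t(vapply(trajectories, function(tr) {
    tr <- as.matrix(tr)
    if (!all(dim(tr) == dims)) stop("trajectories must have equal dimensions")
    as.vector(tr)
  }, numeric(prod(dims))))
  k_max <- min(k_max, n - 1)
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]

  dmat <- as.matrix(stats::dist(scores))
  best_k <- 1L; best_sil <- -Inf; best_labels <- rep(1L, n)
  if (max(abs(dmat)) > 1e-12) {
    for (k in 2:max(2, k_max)) {
      if (k > n - 1) break
      set.seed(mix_seed(seed, k))
      km <- tryCatch(stats::kmeans(scores, centers = k, nstart = 10),
                     error = function(e) NULL)
      if (is.null(km)) next
      sil <- mean_silhouette(dmat, km$cluster)
      if (sil > best_sil + 1e-12) {
        best_sil <- sil; best_k <- k; best_labels <- km$cluster
      }
    }
  }
  labels <- best_labels

  # per-time Gaussian fit per cluster (defined where cluster size >= 2)
  Tlen <- dims[1]; d <- dims[2]
  clusters <- sort(unique(labels))
  gauss <- list()
  for (cl in clusters) {
    members <- which(labels == cl)
    gl <- vector("list", Tlen)
    if (length(members) >= 2) {
      for (t in seq_len(Tlen)) {
        xt <- t(vapply(members, function(i) as.matrix(trajectories[[i]])[t, ],
                       numeric(d)))
        gl[[t]] <- fit_gaussian(xt)
      }
    }
    gauss[[as.character(cl)]] <- gl
  }

  wout <- list()
  if (length(clusters) >= 2) {
    prs <- utils::combn(clusters, 2)
    for (pcol in seq_len(ncol(prs))) {
      c1 <- as.character(prs[1, pcol]); c2 <- as.character(prs[2, pcol])
      if (sum(labels == prs[1, pcol]) < 2 || sum(labels == prs[2, pcol]) < 2) next
      w2 <- vapply(seq_len(Tlen), function(t)
        gaussian_wasserstein2(gauss[[c1]][[t]], gauss[[c2]][[t]]), numeric(1))
      wout[[length(wout) + 1L]] <- data.frame(time = seq_len(Tlen) - 1L,
                                              pair = paste0(c1, "-", c2), w2 = w2)
    }
  }
  list(labels = labels, k = length(clusters), scores = scores,
       cluster_gaussians = gauss,
       wasserstein = if (length(wout)) do.call(rbind, wout) else NULL)
}
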