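# Microstate synthesis: turning a filtered macrostate back into a full
# agent-level state, seeded from a similar existing microstate.
#
# Two principles drive the design. Continuity: a posterior macrostate close
# to a predictive one should be realized by a microstate close to that
# member's microstate, so predictive members and posterior samples are
# paired by a stable matching before synthesis. Local similarity: in spatial
# models, category changes should respect the existing geometry, which the
# one-hot -> rescale -> quantize/error-diffuse pipeline enforces for
# categorical lattices.

#' Stable pairing of predictive members and posterior samples
#'
#' Gale-Shapley stable matching in which each side ranks the other by
#' ascending Euclidean distance in transformed macrostate space (ties broken
#' by lower index) and the posterior samples propose. The resulting pairing
#' minimizes pairwise change in the stable-matching sense, so each posterior
#' sample is synthesized from a nearby predictive microstate.
#'
#' @param pred n x d matrix of predictive macrostates (transformed).
#' @param post n x d matrix of posterior samples (same dimensions).
#' @return integer vector `p` of length n: posterior sample `i` is paired
#'   with predictive member `p[i]`. A permutation with no blocking pair.
#' @export
pair_ensembles <- function(pred, post) {
  pred <- as.matrix(pred); post <- as.matrix(post)
  if (nrow(pred) != nrow(post) || ncol(pred) != ncol(post))
    stop("ensembles must have equal sizes")
  n <- nrow(pred)
  if (n == 0) return(integer(0))
  # distance matrix: rows = posterior (proposers), cols = predictive
  d2 <- outer(rowSums(post^2), rowSums(pred^2), "+") - 2 * post %*% t(pred)
  # proposer preference lists (ascending distance, ties by lower index)
  pref <- t(apply(d2, 1, function(r) order(r, seq_len(n))))
  pref <- matrix(pref, n, n)
  # receiver ranking of proposers: rank[j, i] = how receiver j ranks proposer i
  rank_rec <- matrix(0L, n, n)
  for (j in seq_len(n)) rank_rec[j, order(d2[, j], seq_len(n))] <- seq_len(n)
  next_prop <- rep(1L, n)      # next preference index each proposer will try
  engaged_to <- rep(NA_integer_, n)  # receiver j -> proposer currently held
  free <- seq_len(n)
  while (length(free)) {
    i <- free[1]
    j <- pref[i, next_prop[i]]
    next_prop[i] <- next_prop[i] + 1L
    cur <- engaged_to[j]
    if (is.na(cur)) {
      engaged_to[j] <- i
      free <- free[-1]
    } else if (rank_rec[j, i] < rank_rec[j, cur]) {
      engaged_to[j] <- i
      free <- c(free[-1], cur)
    }
  }
  out <- integer(n)
  out[engaged_to] <- seq_len(n)  # out[proposer] = receiver
  out
}

#' One-hot encoding of a categorical lattice
#'
#' Maps a lattice of category codes to a field of standard basis vectors:
#' a site in category i becomes e_i in R^k. Summing the field over sites
#' yields exactly the category-count vector, which is what lets a count
#' macrostate update act on the field by rescaling.
#'
#' @param grid integer matrix of category codes in `1..k`.
#' @param k number of categories (defaults to `max(grid)`).
#' @return an N x M x k array (`onehot_field`).
#' @export
one_hot_encode <- function(grid, k = max(grid)) {
  grid <- as.matrix(grid)
  if (any(grid < 1 | grid > k | grid != round(grid)))
    stop("grid contains category codes outside 1..k")
  n <- nrow(grid); m <- ncol(grid)
  f <- array(0, c(n, m, k))
  idx <- cbind(rep(seq_len(n), m), rep(seq_len(m), each = n), as.vector(grid))
  f[idx] <- 1
  f
}

#' @rdname one_hot_encode
#' @param field an N x M x k nonnegative array.
#' @return `one_hot_decode()` returns the integer matrix of per-site argmax
#'   categories (ties to the lowest code).
#' @export
one_hot_decode <- function(field) {
  n <- dim(field)[1]; m <- dim(field)[2]
  matrix(apply(matrix(field, n * m, dim(field)[3]), 1, which.max), n, m)
}

#' Rescale a one-hot field to a new count macrostate
#'
#' Multiplies component j at every site by `new_counts[j] / old_counts[j]`,
#' so the field's site-sum moves from the old to the new category counts
#' while every site keeps its local composition. A category appearing in the
#' target but absent from the field (`old == 0, new > 0`) has no spatial
#' information to scale, so its mass is spread uniformly over all sites.
#'
#' @param field N x M x k array.
#' @param old_counts current site-sum of the field (checked).
#' @param new_counts target counts, componentwise >= 0, same total.
#' @return the rescaled N x M x k array, whose site-sum equals `new_counts`.
#' @export
rescale_onehot <- function(field, old_counts, new_counts) {
  k <- dim(field)[3]
  stopifnot(length(old_counts) == k, length(new_counts) == k)
  if (any(new_counts < 0)) stop("new_counts must be nonnegative")
  tot_old <- sum(old_counts); tot_new <- sum(new_counts)
  if (abs(tot_old - tot_new) > 1e-6 * max(1, tot_old))
    stop("old and new counts must have equal totals")
  site_sum <- apply(field, 3, sum)
  if (max(abs(site_sum - old_counts)) > 1e-6 * max(1, tot_old))
    stop("old_counts does not match the field's site-sum")
  nm <- dim(field)[1] * dim(field)[2]
  for (j in seq_len(k)) {
    if (old_counts[j] > 0) {
      field[, , j] <- field[, , j] * (new_counts[j] / old_counts[j])
    } else if (new_counts[j] > 0) {
      field[, , j] <- new_counts[j] / nm
    }
  }
  field
}

#' Quantization configuration
#'
#' Weights of the three-term quantization loss
#' `L(q) = lambda1 |q - s|^2 + lambda2 (-log(c . q + smoothing)) +
#' lambda3 (-log p_model(neighborhood))`:
#' the quantization error, the dissimilarity to the 3 x 3 neighborhood
#' (`c` is the regularized category count around the site, discouraging
#' isolated types), and the neighborhood negative log-probability under a
#' model trained on previous runs.
#'
#' @param lambda1,lambda2,lambda3 nonnegative loss weights (at least one > 0).
#' @param smoothing additive regularizer of the neighborhood counts.
#' @param traversal `"random"` (seeded random permutation; default) or
#'   `"raster"` site-visit order.
#' @return an object of class `quantization_config`.
#' @export
quantization_config <- function(lambda1 = 1, lambda2 = 1, lambda3 = 1,
                                smoothing = 1, traversal = c("random", "raster")) {
  if (lambda1 < 0 || lambda2 < 0 || lambda3 < 0) stop("lambdas must be nonnegative")
  if (lambda1 + lambda2 + lambda3 <= 0) stop("at least one lambda must be > 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 smoothing = smoothing, traversal = match.arg(traversal)),
            class = "quantization_config")
}

# 3x3 neighborhood key: 9 category codes (0 off-lattice) plus one log-binned
# local-mean level per field
neighborhood_key <- function(cats9, field_bins) {
  paste(c(cats9, field_bins), collapse = ",")
}

local_cats9 <- function(eff, i, j) {
  n <- nrow(eff); m <- ncol(eff)
  out <- integer(9)
  idx <- 1L
  for (dj in -1:1) for (di in -1:1) {
    ii <- i + di; jj <- j + dj
    out[idx] <- if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) eff[ii, jj] else 0L
    idx <- idx + 1L
  }
  out
}

local_field_mean <- function(f, i, j) {
  n <- nrow(f); m <- ncol(f)
  ii <- max(1, i - 1):min(n, i + 1)
  jj <- max(1, j - 1):min(m, j + 1)
  mean(f[ii, jj])
}

bin_field_value <- function(x, breaks) {
  findInterval(log1p(x), breaks, all.inside = TRUE)
}

#' Train a neighborhood model from previous runs
#'
#' Histograms every 3 x 3 local configuration (center + neighbors' category
#' codes, plus log-binned local field levels) seen in the training
#' microstate lattices, with add-one smoothing so unseen configurations get
#' finite negative log-probability. Used as the third quantization-loss term
#' to prefer locally plausible quantizations.
#'
#' @param grids list of integer category matrices (training lattices).
#' @param fields_list optional list (parallel to `grids`) of named lists of
#'   numeric field matrices (e.g. local cytokine levels).
#' @param n_bins number of log-spaced bins per field (default 8).
#' @return an object of class `neighborhood_model` with a `counts` table,
#'   total sample size, and per-field bin breaks.
#' @export
build_neighborhood_model <- function(grids, fields_list = NULL, n_bins = 8) {
  if (!length(grids)) stop("training set is empty")
  field_names <- if (!is.null(fields_list)) names(fields_list[[1]]) else character(0)
  # log-spaced bin breaks per field, from the pooled training values
  breaks <- list()
  for (fn in field_names) {
    mx <- max(vapply(fields_list, function(fl) max(fl[[fn]]), 0))
    breaks[[fn]] <- seq(0, max(log1p(mx), 1e-6), length.out = n_bins + 1)[-c(1, n_bins + 1)]
  }
  counts <- new.env(hash = TRUE, parent = emptyenv())
  total <- 0L
  for (g in seq_along(grids)) {
    grid <- grids[[g]]
    n <- nrow(grid); m <- ncol(grid)
    for (j in seq_len(m)) for (i in seq_len(n)) {
      fb <- vapply(field_names, function(fn)
        bin_field_value(local_field_mean(fields_list[[g]][[fn]], i, j), breaks[[fn]]),
        integer(1))
      key <- neighborhood_key(local_cats9(grid, i, j), fb)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      total <- total + 1L
    }
  }
  structure(list(counts = counts, total = total,
                 n_distinct = length(ls(counts)),
                 breaks = breaks, field_names = field_names),
            class = "neighborhood_model")
}

#' @rdname build_neighborhood_model
#' @param model a `neighborhood_model`.
#' @param cats9 integer vector of 9 category codes (0 = off-lattice),
#'   column-major around the site with the center fifth.
#' @param field_values named numeric vector of local field means.
#' @return `neighborhood_neglogp()` returns the smoothed negative
#'   log-probability of the configuration (finite for unseen ones).
#' @export
neighborhood_neglogp <- function(model, cats9, field_values = numeric(0)) {
  fb <- vapply(model$field_names, function(fn)
    bin_field_value(field_values[[fn]], model$breaks[[fn]]), integer(1))
  key <- neighborhood_key(cats9, fb)
  cnt <- model$counts[[key]] %||% 0L
  # add-one smoothing over the observed support plus one unseen bucket
  -log((cnt + 1) / (model$total + model$n_distinct + 1))
}

#' Quantize a rescaled one-hot field back to categories with error diffusion
#'
#' Visits the sites in a seeded random permutation (or raster order). At
#' each site the feasible categories are those whose remaining quota is at
#' least one; the category minimizing the three-term loss of
#' [quantization_config()] is assigned. The quantization residual
#' `delta = q - s` is subtracted uniformly from the not-yet-quantized Moore
#' (8-)neighbors, so total vector mass — and hence the count macrostate — is
#' conserved mid-pass; sites with no unquantized neighbor send their
#' residual to a global pool. Quota bookkeeping makes the final counts equal
#' `target_counts` exactly; a final exchange-repair pass then cancels
#' loss-reducing relabel cycles whenever the loss is site-separable
#' (`lambda2 = lambda3 = 0`), which drives the labeling to the
#' count-constrained optimum.
#'
#' @param field N x M x k nonnegative array (typically a rescaled one-hot
#'   encoding).
#' @param target_counts integer vector summing to N x M (use
#'   [round_largest_remainder()] on real-valued macro targets).
#' @param cfg a [quantization_config()].
#' @param model optional [build_neighborhood_model()] result (needed when
#'   `lambda3 > 0`; ignored otherwise).
#' @param fields optional named list of field matrices passed to the
#'   neighborhood model.
#' @param trace if `TRUE`, also return the per-visit component mass sums
#'   (quantized + unquantized + residual), for conservation diagnostics.
#' @return integer category matrix (with attribute `"trace"` if requested).
#' @export
quantize_error_diffuse <- function(field, target_counts, cfg = quantization_config(),
                                   model = NULL, fields = NULL, trace = FALSE) {
  n <- dim(field)[1]; m <- dim(field)[2]; k <- dim(field)[3]
  target_counts <- as.integer(target_counts)
  if (length(target_counts) != k || any(target_counts < 0) ||
      sum(target_counts) != n * m)
    stop("infeasible target counts")
  use_model <- cfg$lambda3 > 0 && !is.null(model)
  s <- matrix(field, n * m, k)        # working vectors, row per site
  s0 <- s                             # pre-diffusion copy for the repair pass
  labels <- rep(NA_integer_, n * m)
  eff <- matrix(max.col(s, ties.method = "first"), n, m)  # effective categories
  remaining <- target_counts
  residual <- numeric(k)
  order_sites <- switch(cfg$traversal,
                        random = sample.int(n * m),
                        raster = seq_len(n * m))
  basis <- diag(k)
  tr <- if (trace) matrix(0, n * m, k) else NULL
  neighbors8 <- function(i, j) {
    nb <- neighborhood_indices(i, j, n, m)
    nb[!(nb[, 1] == i & nb[, 2] == j), , drop = FALSE]
  }
  for (site in order_sites) {
    i <- (site - 1L) %% n + 1L; j <- (site - 1L) %/% n + 1L
    feas <- which(remaining >= 1L)
    sv <- s[site, ]
    loss <- numeric(length(feas))
    if (cfg$lambda2 > 0 || use_model) {
      cats9 <- local_cats9(eff, i, j)
      nbc <- tabulate(cats9[-5][cats9[-5] > 0], nbins = k)
      fv <- if (use_model && length(model$field_names)) {
        vapply(model$field_names, function(fn)
          local_field_mean(fields[[fn]], i, j), numeric(1))
      } else numeric(0)
    }
    for (qi in seq_along(feas)) {
      q <- feas[qi]
      l <- cfg$lambda1 * sum((basis[q, ] - sv)^2)
      if (cfg$lambda2 > 0)
        l <- l + cfg$lambda2 * (-log(nbc[q] + cfg$smoothing))
      if (use_model) {
        c9 <- cats9; c9[5] <- q
        l <- l + cfg$lambda3 * neighborhood_neglogp(model, c9, fv)
      }
      loss[qi] <- l
    }
    q <- feas[which.min(loss)]
    labels[site] <- q
    eff[i, j] <- q
    remaining[q] <- remaining[q] - 1L
    delta <- basis[q, ] - sv
    nb <- neighbors8(i, j)
    if (nrow(nb)) {
      nb_idx <- nb[, 1] + n * (nb[, 2] - 1L)
      unq <- nb_idx[is.na(labels[nb_idx])]
    } else unq <- integer(0)
    if (length(unq)) {
      share <- delta / length(unq)
      for (u in unq) {
        s[u, ] <- s[u, ] - share
        eff[u] <- which.max(s[u, ])
      }
    } else {
      # no unquantized neighbor to absorb it: bank -delta so that
      # (site vectors) + residual stays constant
      residual <- residual - delta
    }
    if (trace) {
      done <- !is.na(labels)
      mass <- residual + colSums(basis[labels[done], , drop = FALSE])
      if (any(!done)) mass <- mass + colSums(s[!done, , drop = FALSE])
      tr[sum(done), ] <- mass
    }
  }
  labels <- repair_exchange_cycles(labels, s0, cfg, model, fields, n, m)
  out <- matrix(labels, n, m)
  if (trace) attr(out, "trace") <- tr
  out
}

# count of each category among the 8 in-lattice neighbors of every site
neighbor_label_counts <- function(labels_mat, k) {
  n <- nrow(labels_mat); m <- ncol(labels_mat)
  out <- array(0, c(n, m, k))
  for (cat in seq_len(k)) {
    p <- matrix(0, n + 2, m + 2)
    p[2:(n + 1), 2:(m + 1)] <- labels_mat == cat
    out[, , cat] <-
      p[1:n, 1:m] + p[1:n, 2:(m + 1)] + p[1:n, 3:(m + 2)] +
      p[2:(n + 1), 1:m] + p[2:(n + 1), 3:(m + 2)] +
      p[3:(n + 2), 1:m] + p[3:(n + 2), 2:(m + 1)] + p[3:(n + 2), 3:(m + 2)]
  }
  out
}

# per-site per-category loss against the pre-diffusion field and the
# current labeling (neighborhood terms recomputed from the labels)
site_loss_table <- function(labels, s0, cfg, model, fields, n, m) {
  k <- ncol(s0)
  L <- cfg$lambda1 * (rowSums(s0^2) - 2 * s0 +
                        matrix(1, nrow(s0), k))
  if (cfg$lambda2 > 0) {
    nbc <- neighbor_label_counts(matrix(labels, n, m), k)
    L <- L - cfg$lambda2 * log(matrix(nbc, n * m, k) + cfg$smoothing)
  }
  if (cfg$lambda3 > 0 && !is.null(model)) {
    eff <- matrix(labels, n, m)
    for (site in seq_len(n * m)) {
      i <- (site - 1L) %% n + 1L; j <- (site - 1L) %/% n + 1L
      cats9 <- local_cats9(eff, i, j)
      fv <- if (length(model$field_names)) {
        vapply(model$field_names, function(fn)
          local_field_mean(fields[[fn]], i, j), numeric(1))
      } else numeric(0)
      for (cat in seq_len(k)) {
        c9 <- cats9; c9[5] <- cat
        L[site, cat] <- L[site, cat] +
          cfg$lambda3 * neighborhood_neglogp(model, c9, fv)
      }
    }
  }
  L
}

# Count-preserving exchange repair: cancel negative-cost relabel cycles
# (one site moves per arc of a category cycle, so all counts are
# preserved). For a site-separable loss (lambda2 = lambda3 = 0) this is the
# transportation-problem optimality condition, so it terminates at the
# count-constrained optimum; with neighborhood terms active the loss table
# is recomputed from the labels after every cancellation and the loop is
# iteration-capped.
repair_exchange_cycles <- function(labels, s0, cfg, model, fields, n, m,
                                   max_iter = 400L) {
  k <- ncol(s0)
  separable <- cfg$lambda2 == 0 && (cfg$lambda3 == 0 || is.null(model))
  cycles <- all_simple_cycles(k)
  L <- site_loss_table(labels, s0, cfg, model, fields, n, m)
  for (iter in seq_len(max_iter)) {
    # W[a, b]: cheapest single-site relabel a -> b, with its site
    W <- matrix(Inf, k, k)
    arg <- matrix(NA_integer_, k, k)
    for (a in seq_len(k)) {
      sa <- which(labels == a)
      if (!length(sa)) next
      ca <- L[sa, a]
      for (b in seq_len(k)) {
        if (b == a) next
        d <- L[sa, b] - ca
        i <- which.min(d)
        W[a, b] <- d[i]
        arg[a, b] <- sa[i]
      }
    }
    best <- NULL; best_w <- -1e-9
    for (cy in cycles) {
      arcs <- cbind(cy, c(cy[-1], cy[1]))
      w <- sum(W[arcs])
      if (is.finite(w) && w < best_w) { best_w <- w; best <- arcs }
    }
    if (is.null(best)) break
    labels[arg[best]] <- best[, 2]
    if (!separable)
      L <- site_loss_table(labels, s0, cfg, model, fields, n, m)
  }
  labels
}

# all directed simple cycles (length >= 2) over nodes 1..k, each counted once
all_simple_cycles <- function(k) {
  cycles <- list()
  extend <- function(path) {
    last <- path[length(path)]
    for (v in seq_len(k)) {
      if (v == path[1] && length(path) >= 2) {
        cycles[[length(cycles) + 1L]] <<- path
      } else if (v > path[1] && !(v %in% path)) {
        extend(c(path, v))
      }
    }
  }
  for (start in seq_len(k)) extend(start)
  cycles
}

#' Rescale a molecular field to a new total
#'
#' Multiplies the whole field by `new_total / old_total`, which moves the
#' field's macrostate total while preserving its spatial correlation
#' structure exactly. A zero field with a positive target has no spatial
#' information, so the mass is spread uniformly.
#'
#' @param field numeric matrix (nonnegative).
#' @param new_total target total (>= 0).
#' @return the rescaled matrix.
#' @export
rescale_molecular <- function(field, new_total) {
  if (new_total < 0) stop("new_total must be nonnegative")
  old_total <- sum(field)
  if (old_total > 0) {
    field * (new_total / old_total)
  } else if (new_total > 0) {
    matrix(new_total / length(field), nrow(field), ncol(field))
  } else {
    field * 0
  }
}

# integer epithelial/endothelial/immune/apoptosis targets from a raw macro
viral_integer_targets <- function(target, nm) {
  v <- if (inherits(target, "abmkf_macro")) target$values else target
  epi <- round_largest_remainder(
    v[c("epi_healthy", "epi_infected", "epi_necrosed", "epi_apoptosed", "epi_empty")],
    total = nm)
  endo <- round_largest_remainder(
    v[c("endo_normal", "endo_activated", "endo_dead")], total = nm)
  list(values = v, epi = epi, endo = endo,
       immune = max(0L, as.integer(round(v[["immune_count"]]))),
       apop = max(0L, as.integer(round(v[["apoptosis_by_virus"]]))))
}

relabel_random <- function(grid, target_counts) {
  k <- length(target_counts)
  cur <- tabulate(grid, nbins = k)
  delta <- target_counts - cur
  if (all(delta == 0)) return(grid)
  pool <- integer(0)
  for (cat in which(delta < 0)) {
    sites <- which(grid == cat)
    take <- if (length(sites) == 1) sites else sample(sites, -delta[cat])
    pool <- c(pool, take)
  }
  pool <- if (length(pool) > 1) sample(pool) else pool
  at <- 1L
  for (cat in which(delta > 0)) {
    idx <- pool[at:(at + delta[cat] - 1L)]
    grid[idx] <- cat
    at <- at + delta[cat]
  }
  grid
}

rescale_all_fields <- function(micro, tv) {
  micro$virus <- rescale_molecular(micro$virus, tv[["virus_total"]])
  micro$cytokines$antiviral <- rescale_molecular(micro$cytokines$antiviral,
                                                 tv[["antiviral_total"]])
  micro$cytokines$proinflam <- rescale_molecular(micro$cytokines$proinflam,
                                                 tv[["proinflam_total"]])
  micro$cytokines$damps <- rescale_molecular(micro$cytokines$damps,
                                             tv[["damps_total"]])
  micro
}

adjust_immune <- function(imm, target, n, m, weight = NULL) {
  cur <- nrow(imm)
  if (target < cur) {
    keep <- sample.int(cur, target)
    imm <- imm[keep, , drop = FALSE]
  } else if (target > cur) {
    add <- target - cur
    sites <- if (is.null(weight) || sum(weight) <= 0) {
      sample.int(n * m, add, replace = TRUE)
    } else {
      sample.int(n * m, add, replace = TRUE, prob = as.vector(weight))
    }
    imm <- rbind(imm, cbind(row = (sites - 1L) %% n + 1L,
                            col = (sites - 1L) %/% n + 1L))
  }
  imm
}

#' Simple (spatially blind) viral microstate synthesis
#'
#' Epithelial and endothelial lattices are driven to the target category
#' counts by relabeling uniformly chosen sites; the number of relabeled
#' sites equals half the L1 distance between the count vectors, the minimum
#' possible. Molecular fields are rescaled; immune agents are added at
#' uniform positions or removed uniformly. Fast and macrostate-exact, but
#' blind to the infection's geometry: newly infected sites typically land
#' outside existing hot-spots.
#'
#' @param target an [macro_vector()] (raw units, viral schema state
#'   components) or equivalent named vector.
#' @param seed_micro a `viral_microstate` (continuity seed).
#' @return a `viral_microstate` summarizing to the rounded target.
#' @export
simple_synthesis_viral <- function(target, seed_micro) {
  n <- nrow(seed_micro$epithelium); m <- ncol(seed_micro$epithelium)
  tg <- viral_integer_targets(target, n * m)
  out <- seed_micro
  out$epithelium <- relabel_random(seed_micro$epithelium, tg$epi)
  out$endothelium <- relabel_random(seed_micro$endothelium, tg$endo)
  out <- rescale_all_fields(out, tg$values)
  out$immune <- adjust_immune(seed_micro$immune, tg$immune, n, m)
  out$apoptosis_by_virus <- tg$apop
  out
}

#' Spatially aware viral microstate synthesis
#'
#' Epithelium and endothelium are each passed through the
#' one-hot encode -> rescale -> quantize/error-diffuse pipeline, so count
#' changes are realized where the corresponding category mass already
#' lives and hot-spots are preserved instead of fragmented. Molecular
#' fields are rescaled (spatial correlations preserved); new immune agents
#' are placed proportional to the proinflammatory field.
#'
#' @param target an [macro_vector()] (raw units) or named vector.
#' @param seed_micro a `viral_microstate`.
#' @param cfg a [quantization_config()].
#' @param models optional named list of [build_neighborhood_model()] results
#'   (`epithelium`, `endothelium`).
#' @return a `viral_microstate` summarizing to the rounded target.
#' @export
spatial_synthesis_viral <- function(target, seed_micro,
                                    cfg = quantization_config(),
                                    models = NULL) {
  n <- nrow(seed_micro$epithelium); m <- ncol(seed_micro$epithelium)
  tg <- viral_integer_targets(target, n * m)
  out <- seed_micro
  fields <- list(virus = seed_micro$virus,
                 antiviral = seed_micro$cytokines$antiviral,
                 proinflam = seed_micro$cytokines$proinflam,
                 damps = seed_micro$cytokines$damps)

  epi_f <- one_hot_encode(seed_micro$epithelium, k = 5)
  epi_f <- rescale_onehot(epi_f, tabulate(seed_micro$epithelium, nbins = 5), tg$epi)
  out$epithelium <- quantize_error_diffuse(epi_f, tg$epi, cfg,
                                           model = models$epithelium, fields = fields)

  endo_f <- one_hot_encode(seed_micro$endothelium, k = 3)
  endo_f <- rescale_onehot(endo_f, tabulate(seed_micro$endothelium, nbins = 3), tg$endo)
  out$endothelium <- quantize_error_diffuse(endo_f, tg$endo, cfg,
                                            model = models$endothelium, fields = fields)

  out <- rescale_all_fields(out, tg$values)
  out$immune <- adjust_immune(seed_micro$immune, tg$immune, n, m,
                              weight = out$cytokines$proinflam)
  out$apoptosis_by_virus <- tg$apop
  out
}
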