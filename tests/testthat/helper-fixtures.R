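# Shared fixtures and independent oracles, built in code at test time.

# small world for fast driver tests
small_wsg_params <- function() {
  wsg_params(world_width = 15, world_height = 15, init_wolves = 15,
             init_sheep = 30, init_grass_density = 0.5)
}

# evolve a single-seed infection into a hot-spot microstate
make_hotspot_micro <- function(params = viral_params(n = 25), steps = 60,
                               min_infected = 5) {
  repeat {
    vm <- init_viral(params, 1)
    for (t in seq_len(steps)) vm <- step_viral(vm, params)
    if (summarize_viral(vm)$values[["epi_infected"]] >= min_infected) return(vm)
  }
}

# random valid macro target near a viral seed state's summary
perturb_viral_target <- function(seed_micro, max_shift = 10) {
  sm <- summarize_viral(seed_micro)$values
  nm <- length(seed_micro$epithelium)
  epi <- sm[5:9]
  for (rep in 1:3) {
    from <- sample(which(epi > 0), 1)
    to <- sample(5, 1)
    amt <- sample.int(min(max_shift, epi[from]), 1)
    epi[from] <- epi[from] - amt; epi[to] <- epi[to] + amt
  }
  endo <- sm[10:12]
  from <- sample(which(endo > 0), 1); to <- sample(3, 1)
  amt <- sample.int(min(max_shift, endo[from]), 1)
  endo[from] <- endo[from] - amt; endo[to] <- endo[to] + amt
  tv <- sm
  tv[5:9] <- epi; tv[10:12] <- endo
  tv[1:4] <- sm[1:4] * stats::runif(4, 0.5, 1.5)
  tv["immune_count"] <- max(0, round(sm["immune_count"] + sample(-2:3, 1)))
  tv
}

# enumeration oracle: all labelings of n sites with exact category counts
enum_labelings <- function(counts) {
  k <- length(counts); n <- sum(counts)
  out <- list()
  rec <- function(assigned, rem) {
    if (length(assigned) == n) {
      out[[length(out) + 1L]] <<- assigned
      return()
    }
    for (cat in seq_len(k)) if (rem[cat] > 0) {
      rem2 <- rem; rem2[cat] <- rem2[cat] - 1L
      rec(c(assigned, cat), rem2)
    }
  }
  rec(integer(0), as.integer(counts))
  out
}

# total squared quantization error of a labeling against a flattened field
labeling_cost <- function(labels, s0) {
  k <- ncol(s0)
  sum(vapply(seq_along(labels), function(i)
    sum((as.numeric(seq_len(k) == labels[i]) - s0[i, ])^2), numeric(1)))
}

# brute-force stable-matching check: TRUE if the pairing has no blocking
# pair under mutual distance preferences
has_blocking_pair <- function(pred, post, pairing) {
  n <- nrow(pred)
  d2 <- outer(rowSums(post^2), rowSums(pred^2), "+") - 2 * post %*% t(pred)
  partner_of_pred <- integer(n)
  partner_of_pred[pairing] <- seq_len(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (pairing[i] == j) next
    prefers_i <- d2[i, j] < d2[i, pairing[i]]
    prefers_j <- d2[i, j] < d2[partner_of_pred[j], j]
    if (prefers_i && prefers_j) return(TRUE)
  }
  FALSE
}
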