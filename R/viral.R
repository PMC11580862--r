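# Minimal spatial viral-infection agent-based model.
#
# A deliberately simplified stand-in for a full anti-viral immune-response
# ABM: a categorical epithelial lattice (healthy / infected / necrosed /
# apoptosed / empty), a 3-state endothelial lattice (normal / activated /
# dead), molecular fields (extracellular virus plus three cytokine-like
# fields: antiviral, proinflammatory, and a DAMP-like damage signal), and
# mobile immune agents that chemotax up the proinflammatory gradient. The
# point of the model is qualitative: infections grow as spatial hot-spots,
# which is what motivates spatially aware microstate synthesis.
#
# Lattices are integer matrices; fields are numeric matrices. Diffusion is
# explicit 5-point-stencil with zero-flux boundaries, stable for
# diffusion coefficients <= 1/4, followed by multiplicative decay.

#' Epithelial and endothelial category labels
#'
#' Ordered category sets used by the one-hot encoding: epithelial sites take
#' one of five states, endothelial sites one of three.
#' @export
EPI_CATEGORIES <- c("healthy", "infected", "necrosed", "apoptosed", "empty")

#' @rdname EPI_CATEGORIES
#' @export
ENDO_CATEGORIES <- c("normal", "activated", "dead")

#' Minimal viral model parameters
#'
#' Rates are per step; the lattice defaults to 51 x 51 (use 25 for
#' desk-scale runs). A healthy site becomes infected with probability
#' 1 - exp(-infect_rate x local virus); infected sites emit virus and both
#' cytokines and die by apoptosis (rate modulated upward by the local
#' antiviral level) or necrosis; necrotic sites emit the DAMP field.
#' Endothelium activates above `endo_activate_threshold` of local
#' proinflammatory cytokine and dies above `endo_death_threshold` of local
#' DAMPs.
#'
#' @param infect_rate infection-hazard coefficient per unit local virus.
#' @param virus_production virus emitted per infected site per step.
#' @param apoptosis_rate,necrosis_rate baseline per-step death probabilities
#'   of infected sites.
#' @param proinflam_production,antiviral_production cytokine emitted per
#'   infected site per step.
#' @param damps_production DAMPs emitted per necrotic site per step.
#' @param diffusion named or scalar diffusion coefficients (<= 0.25).
#' @param decay named or scalar per-step decay fractions in `[0, 1]`.
#' @param kill_prob probability an immune agent kills a co-located infected
#'   site in one step.
#' @param recruit_rate expected immune arrivals per unit total
#'   proinflammatory cytokine per step.
#' @param endo_activate_threshold,endo_death_threshold local cytokine / DAMP
#'   levels above which endothelium activates / dies.
#' @param init_virus virus load deposited on each seed infection site.
#' @param n,m lattice dimensions.
#' @return an object of class `viral_params`.
#' @export
viral_params <- function(infect_rate = 0.1, virus_production = 1.0,
                         apoptosis_rate = 0.05, necrosis_rate = 0.02,
                         proinflam_production = 1.0, antiviral_production = 0.5,
                         damps_production = 1.0,
                         diffusion = 0.2,
                         decay = c(virus = 0.15, antiviral = 0.12,
                                   proinflam = 0.12, damps = 0.12),
                         kill_prob = 0.5, recruit_rate = 5e-4,
                         endo_activate_threshold = 1.0,
                         endo_death_threshold = 2.0,
                         init_virus = 5.0, n = 51, m = n) {
  fields <- c("virus", "antiviral", "proinflam", "damps")
  expand <- function(x) {
    if (length(x) == 1) x <- stats::setNames(rep(x, 4), fields)
    stopifnot(all(fields %in% names(x)))
    x[fields]
  }
  p <- list(infect_rate = infect_rate, virus_production = virus_production,
            apoptosis_rate = apoptosis_rate, necrosis_rate = necrosis_rate,
            proinflam_production = proinflam_production,
            antiviral_production = antiviral_production,
            damps_production = damps_production,
            diffusion = expand(diffusion), decay = expand(decay),
            kill_prob = kill_prob, recruit_rate = recruit_rate,
            endo_activate_threshold = endo_activate_threshold,
            endo_death_threshold = endo_death_threshold,
            init_virus = init_virus, n = as.integer(n), m = as.integer(m))
  rates <- c(p$infect_rate, p$virus_production, p$apoptosis_rate, p$necrosis_rate,
             p$proinflam_production, p$antiviral_production, p$damps_production,
             p$recruit_rate, p$init_virus)
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (p$kill_prob < 0 || p$kill_prob > 1) stop("kill_prob must lie in [0, 1]")
  if (any(p$diffusion < 0) || any(p$diffusion > 0.25))
    stop("diffusion coefficients must lie in [0, 0.25] for stability")
  if (any(p$decay < 0) || any(p$decay > 1)) stop("decay fractions must lie in [0, 1]")
  if (p$n < 1 || p$m < 1) stop("lattice dimensions must be >= 1")
  structure(p, class = "viral_params")
}

zero_field <- function(n, m) matrix(0, n, m)

#' Initialize a viral microstate at infection onset
#'
#' All epithelium healthy except `n_seed` uniformly placed infected sites,
#' each carrying `init_virus` extracellular virus; endothelium all normal;
#' cytokines zero; no immune agents.
#'
#' @param params a [viral_params()].
#' @param n_seed number of seed infection sites (<= lattice size).
#' @return an object of class `viral_microstate` with elements `epithelium`,
#'   `endothelium` (integer category matrices), `virus`, `cytokines` (list of
#'   numeric matrices: antiviral, proinflam, damps), `immune` (k x 2 matrix
#'   of row/col positions) and `apoptosis_by_virus` (counter).
#' @export
init_viral <- function(params, n_seed = 1) {
  n <- params$n; m <- params$m
  if (n_seed > n * m) stop("n_seed exceeds lattice size")
  epi <- matrix(1L, n, m)
  virus <- zero_field(n, m)
  if (n_seed > 0) {
    sites <- sample.int(n * m, n_seed)
    epi[sites] <- 2L
    virus[sites] <- params$init_virus
  }
  structure(list(
    epithelium = epi,
    endothelium = matrix(1L, n, m),
    virus = virus,
    cytokines = list(antiviral = zero_field(n, m),
                     proinflam = zero_field(n, m),
                     damps = zero_field(n, m)),
    immune = matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))),
    apoptosis_by_virus = 0L
  ), class = "viral_microstate")
}

# explicit zero-flux 5-point diffusion then multiplicative decay;
# the diffusion substep conserves total mass exactly
diffuse_decay <- function(f, d, decay) {
  if (d > 0) {
    n <- nrow(f); m <- ncol(f)
    up    <- rbind(f[1, , drop = FALSE], f[-n, , drop = FALSE])
    down  <- rbind(f[-1, , drop = FALSE], f[n, , drop = FALSE])
    left  <- cbind(f[, 1, drop = FALSE], f[, -m, drop = FALSE])
    right <- cbind(f[, -1, drop = FALSE], f[, m, drop = FALSE])
    # replicated edge rows make the missing-neighbor flux vanish (zero-flux)
    f <- f + d * (up + down + left + right - 4 * f)
  }
  f * (1 - decay)
}

# 3x3 neighborhood maximum by index (used for immune chemotaxis)
neighborhood_indices <- function(i, j, n, m) {
  di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
  ii <- i + di; jj <- j + dj
  ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= m
  cbind(ii[ok], jj[ok])
}

#' Advance the minimal viral model one step
#'
#' Order: infection of healthy sites by local virus; infected-site emission
#' (virus, proinflammatory, antiviral) and death (apoptosis, modulated by
#' the local antiviral level and counted in `apoptosis_by_virus`, or
#' necrosis); DAMP emission by necrotic sites; field diffusion and decay;
#' immune-agent chemotaxis (one step toward the highest proinflammatory
#' 3 x 3 neighbor, ties broken at random), killing of co-located infected
#' sites (to apoptosed, not counted as virus-killed); Poisson immune
#' recruitment placed proportional to the proinflammatory field; endothelial
#' activation and death by local cytokine / DAMP thresholds.
#'
#' @param micro a `viral_microstate`.
#' @param params a [viral_params()].
#' @return the next `viral_microstate`.
#' @export
step_viral <- function(micro, params) {
  n <- params$n; m <- params$m
  epi <- micro$epithelium
  endo <- micro$endothelium
  virus <- micro$virus
  cyt <- micro$cytokines
  killed <- micro$apoptosis_by_virus

  # infection of healthy sites
  healthy <- epi == 1L
  if (any(healthy)) {
    p_inf <- 1 - exp(-params$infect_rate * virus[healthy])
    inf <- healthy
    inf[healthy] <- stats::runif(sum(healthy)) < p_inf
    epi[inf] <- 2L
  }

  # infected-site emission and death
  infected <- which(epi == 2L)
  if (length(infected)) {
    virus[infected] <- virus[infected] + params$virus_production
    cyt$proinflam[infected] <- cyt$proinflam[infected] + params$proinflam_production
    cyt$antiviral[infected] <- cyt$antiviral[infected] + params$antiviral_production
    p_apop <- pmin(1, params$apoptosis_rate * (1 + cyt$antiviral[infected]))
    p_necr <- pmin(pmax(0, 1 - p_apop), params$necrosis_rate)
    u <- stats::runif(length(infected))
    apop <- u < p_apop
    necr <- !apop & u < p_apop + p_necr
    epi[infected[apop]] <- 4L
    epi[infected[necr]] <- 3L
    killed <- killed + sum(apop)
  }

  # DAMP emission by necrotic sites
  necrosed <- epi == 3L
  if (any(necrosed))
    cyt$damps[necrosed] <- cyt$damps[necrosed] + params$damps_production

  # field transport
  virus <- diffuse_decay(virus, params$diffusion[["virus"]], params$decay[["virus"]])
  cyt$antiviral <- diffuse_decay(cyt$antiviral, params$diffusion[["antiviral"]],
                                 params$decay[["antiviral"]])
  cyt$proinflam <- diffuse_decay(cyt$proinflam, params$diffusion[["proinflam"]],
                                 params$decay[["proinflam"]])
  cyt$damps <- diffuse_decay(cyt$damps, params$diffusion[["damps"]],
                             params$decay[["damps"]])

  # immune agents: chemotaxis then killing
  imm <- micro$immune
  if (nrow(imm)) {
    for (a in seq_len(nrow(imm))) {
      nb <- neighborhood_indices(imm[a, 1], imm[a, 2], n, m)
      lv <- cyt$proinflam[nb]
      best <- which(lv == max(lv))
      pick <- if (length(best) == 1) best else sample(best, 1)
      imm[a, ] <- nb[pick, ]
    }
    at_infected <- epi[imm] == 2L
    if (any(at_infected)) {
      kills <- at_infected & stats::runif(nrow(imm)) < params$kill_prob
      epi[imm[kills, , drop = FALSE]] <- 4L
    }
  }

  # recruitment proportional to local proinflammatory cytokine
  total_pro <- sum(cyt$proinflam)
  if (total_pro > 0 && params$recruit_rate > 0) {
    n_new <- stats::rpois(1, params$recruit_rate * total_pro)
    if (n_new > 0) {
      sites <- sample.int(n * m, n_new, replace = TRUE, prob = as.vector(cyt$proinflam))
      imm <- rbind(imm, cbind(row = (sites - 1L) %% n + 1L,
                              col = (sites - 1L) %/% n + 1L))
    }
  }

  # endothelium: activation and death thresholds on local fields
  endo[endo == 1L & cyt$proinflam > params$endo_activate_threshold] <- 2L
  endo[endo != 3L & cyt$damps > params$endo_death_threshold] <- 3L

  structure(list(epithelium = epi, endothelium = endo, virus = virus,
                 cytokines = cyt, immune = imm, apoptosis_by_virus = killed),
            class = "viral_microstate")
}

#' Summarize a viral microstate
#'
#' Ordered macrostate: totals of extracellular virus and of each cytokine
#' field, the five epithelial category counts, the three endothelial
#' category counts, the immune-agent count, and the running count of
#' epithelial cells apoptosed by the virus.
#'
#' @param micro a `viral_microstate`.
#' @param schema optional schema; defaults to [default_viral_schema()]
#'   without parameters.
#' @return an [macro_vector()].
#' @export
summarize_viral <- function(micro, schema = NULL) {
  if (is.null(schema)) schema <- default_viral_schema(parameters = character(0))
  epi_counts <- tabulate(micro$epithelium, nbins = 5)
  endo_counts <- tabulate(micro$endothelium, nbins = 3)
  vals <- c(sum(micro$virus), sum(micro$cytokines$antiviral),
            sum(micro$cytokines$proinflam), sum(micro$cytokines$damps),
            epi_counts, endo_counts, nrow(micro$immune), micro$apoptosis_by_virus)
  macro_vector(vals, schema)
}

#' Simulate a viral macrostate trajectory
#'
#' @param params a [viral_params()].
#' @param horizon number of steps.
#' @param n_seed seed infection sites for [init_viral()].
#' @param keep_micro if `TRUE`, also keep every microstate.
#' @return list with `macro` (data frame, one named column per component),
#'   `micro` (optional list) and `final_micro`.
#' @export
simulate_viral <- function(params, horizon, n_seed = 1, keep_micro = FALSE) {
  micro <- init_viral(params, n_seed)
  sm <- summarize_viral(micro)
  out <- matrix(0, horizon + 1, length(sm$values))
  colnames(out) <- sm$schema$names
  out[1, ] <- sm$values
  micros <- if (keep_micro) vector("list", horizon + 1) else NULL
  if (keep_micro) micros[[1]] <- micro
  for (t in seq_len(horizon)) {
    micro <- step_viral(micro, params)
    out[t + 1, ] <- summarize_viral(micro)$values
    if (keep_micro) micros[[t + 1]] <- micro
  }
  list(macro = data.frame(time = 0:horizon, out, check.names = FALSE),
       micro = micros, final_micro = micro)
}
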