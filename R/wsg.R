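# Wolf-Sheep-Grass predator-prey agent-based model.
#
# Wolves and sheep are mobile agents on a continuous toroidal plane with an
# internal energy counter; grass is an on/off lattice with a regrowth timer.
# One synchronous step: move -> eat -> reproduce -> die -> regrow. The model
# is spatially well mixed (random-walk movement), which is what makes the
# uniform-random microstate synthesis in synthesize_wsg() appropriate.
#
# Agents are stored as n x 4 matrices with columns x, y, heading, energy.

AGENT_COLS <- c("x", "y", "heading", "energy")

empty_agents <- function() {
  matrix(numeric(0), 0, 4, dimnames = list(NULL, AGENT_COLS))
}

#' Wolf-sheep-grass model parameters
#'
#' Defaults follow the classic predator-prey model this simulator
#' re-implements: reproduction probabilities of 5% (wolves) and 4% (sheep)
#' per step, energy gains of 20 and 4 from eating, a 30-step grass regrowth
#' timer, and a 51 x 51 patch world seeded with 50 wolves, 100 sheep and
#' half the patches grassy.
#'
#' @param wolf_reproduce_prob,sheep_reproduce_prob per-step reproduction
#'   probabilities in `[0, 1]`.
#' @param wolf_gain_from_food,sheep_gain_from_food energy gained by eating.
#' @param grass_regrowth_time steps for an eaten patch to regrow (>= 1).
#' @param world_width,world_height lattice dimensions in patches.
#' @param init_wolves,init_sheep initial agent counts.
#' @param init_grass_density initial probability that a patch is grassy.
#' @return an object of class `wsg_params`.
#' @export
wsg_params <- function(wolf_reproduce_prob = 0.05, sheep_reproduce_prob = 0.04,
                       wolf_gain_from_food = 20, sheep_gain_from_food = 4,
                       grass_regrowth_time = 30,
                       world_width = 51, world_height = 51,
                       init_wolves = 50, init_sheep = 100,
                       init_grass_density = 0.5) {
  p <- list(wolf_reproduce_prob = wolf_reproduce_prob,
            sheep_reproduce_prob = sheep_reproduce_prob,
            wolf_gain_from_food = wolf_gain_from_food,
            sheep_gain_from_food = sheep_gain_from_food,
            grass_regrowth_time = as.integer(grass_regrowth_time),
            world_width = as.integer(world_width),
            world_height = as.integer(world_height),
            init_wolves = as.integer(init_wolves),
            init_sheep = as.integer(init_sheep),
            init_grass_density = init_grass_density)
  if (p$wolf_reproduce_prob < 0 || p$wolf_reproduce_prob > 1 ||
      p$sheep_reproduce_prob < 0 || p$sheep_reproduce_prob > 1)
    stop("reproduction probabilities must lie in [0, 1]")
  if (p$wolf_gain_from_food < 0 || p$sheep_gain_from_food < 0)
    stop("energy gains must be nonnegative")
  if (p$grass_regrowth_time < 1) stop("grass_regrowth_time must be >= 1")
  if (p$world_width < 1 || p$world_height < 1) stop("world dimensions must be >= 1")
  if (p$init_wolves < 0 || p$init_sheep < 0) stop("initial counts must be >= 0")
  if (p$init_grass_density < 0 || p$init_grass_density > 1)
    stop("init_grass_density must lie in [0, 1]")
  structure(p, class = "wsg_params")
}

new_agents <- function(n, width, height, energy) {
  m <- cbind(x = stats::runif(n, 0, width),
             y = stats::runif(n, 0, height),
             heading = stats::runif(n, 0, 2 * pi),
             energy = energy)
  if (n == 0) m <- empty_agents()
  m
}

#' Initialize a wolf-sheep-grass microstate
#'
#' Agents are placed uniformly at random with uniform headings and energies
#' drawn uniformly in (0, 2 x gain_from_food]; each patch is grassy
#' independently with probability `init_grass_density`, and bare patches get
#' a uniform-random regrowth counter in `[1, grass_regrowth_time]`.
#'
#' @param params a [wsg_params()] object.
#' @return an object of class `wsg_microstate` with elements `wolves`,
#'   `sheep` (agent matrices), `grass_alive` (logical matrix) and
#'   `grass_counter` (integer matrix).
#' @export
init_wsg <- function(params) {
  stopifnot(inherits(params, "wsg_params"))
  w <- params$world_width; h <- params$world_height
  wolves <- new_agents(params$init_wolves, w, h,
                       stats::runif(params$init_wolves) * 2 * params$wolf_gain_from_food)
  sheep <- new_agents(params$init_sheep, w, h,
                      stats::runif(params$init_sheep) * 2 * params$sheep_gain_from_food)
  alive <- matrix(stats::runif(w * h) < params$init_grass_density, w, h)
  counter <- matrix(0L, w, h)
  ndead <- sum(!alive)
  if (ndead > 0)
    counter[!alive] <- sample.int(params$grass_regrowth_time, ndead, replace = TRUE)
  structure(list(wolves = wolves, sheep = sheep,
                 grass_alive = alive, grass_counter = counter),
            class = "wsg_microstate")
}

# toroidal patch index (1-based, column-major over a width x height lattice)
patch_index <- function(agents, width, height) {
  px <- floor(agents[, 1]) %% width
  py <- floor(agents[, 2]) %% height
  as.integer(px + width * py + 1)
}

move_agents <- function(agents, width, height) {
  n <- nrow(agents)
  if (n == 0) return(agents)
  turn <- stats::runif(n, -50, 50) * pi / 180
  hd <- (agents[, 3] + turn) %% (2 * pi)
  agents[, 1] <- (agents[, 1] + cos(hd)) %% width
  agents[, 2] <- (agents[, 2] + sin(hd)) %% height
  agents[, 3] <- hd
  agents[, 4] <- agents[, 4] - 1
  agents
}

reproduce_agents <- function(agents, prob) {
  n <- nrow(agents)
  if (n == 0 || prob <= 0) return(agents)
  rep_idx <- which(stats::runif(n) < prob)
  if (!length(rep_idx)) return(agents)
  agents[rep_idx, 4] <- agents[rep_idx, 4] / 2
  children <- agents[rep_idx, , drop = FALSE]
  children[, 3] <- stats::runif(length(rep_idx), 0, 2 * pi)
  rbind(agents, children)
}

#' Advance the wolf-sheep-grass model one step
#'
#' Substep order: (1) every agent turns uniformly in +/-50 degrees, moves one
#' patch-length forward on the torus and pays one energy; (2) every sheep on
#' a grassy patch eats it (patch dies, counter reset to the regrowth time);
#' every wolf sharing a patch with sheep eats exactly one, chosen uniformly;
#' (3) each surviving agent reproduces with its species' probability,
#' splitting its energy equally with the child spawned at its position;
#' (4) agents with negative energy die; (5) bare-patch counters decrement and
#' patches whose counter reaches zero regrow.
#'
#' @param micro a `wsg_microstate`.
#' @param params a [wsg_params()].
#' @return the next `wsg_microstate`.
#' @export
step_wsg <- function(micro, params) {
  w <- params$world_width; h <- params$world_height
  wolves <- move_agents(micro$wolves, w, h)
  sheep <- move_agents(micro$sheep, w, h)
  alive <- micro$grass_alive
  counter <- micro$grass_counter

  # sheep graze (synchronous: patch aliveness read at substep start)
  if (nrow(sheep) > 0) {
    sp <- patch_index(sheep, w, h)
    grazing <- alive[sp]
    if (any(grazing)) {
      sheep[grazing, 4] <- sheep[grazing, 4] + params$sheep_gain_from_food
      eaten <- unique(sp[grazing])
      alive[eaten] <- FALSE
      counter[eaten] <- params$grass_regrowth_time
    }
  }

  # wolves hunt: each wolf eats at most one co-located sheep, distinct prey
  if (nrow(wolves) > 0 && nrow(sheep) > 0) {
    wp <- patch_index(wolves, w, h)
    sp <- patch_index(sheep, w, h)
    shared <- intersect(unique(wp), unique(sp))
    if (length(shared)) {
      dead_sheep <- integer(0)
      for (p in shared) {
        wi <- which(wp == p)
        si <- which(sp == p)
        k <- min(length(wi), length(si))
        eaters <- if (length(wi) == 1) wi else sample(wi, k)
        prey <- if (length(si) == 1) si else sample(si, k)
        eaters <- eaters[seq_len(k)]
        wolves[eaters, 4] <- wolves[eaters, 4] + params$wolf_gain_from_food
        dead_sheep <- c(dead_sheep, prey[seq_len(k)])
      }
      if (length(dead_sheep))
        sheep <- sheep[-dead_sheep, , drop = FALSE]
    }
  }

  wolves <- reproduce_agents(wolves, params$wolf_reproduce_prob)
  sheep <- reproduce_agents(sheep, params$sheep_reproduce_prob)

  wolves <- wolves[wolves[, 4] >= 0, , drop = FALSE]
  sheep <- sheep[sheep[, 4] >= 0, , drop = FALSE]

  dead <- counter > 0L
  counter[dead] <- counter[dead] - 1L
  alive[dead & counter == 0L] <- TRUE

  structure(list(wolves = wolves, sheep = sheep,
                 grass_alive = alive, grass_counter = counter),
            class = "wsg_microstate")
}

#' Summarize a wolf-sheep-grass microstate
#'
#' The macrostate of this model is the wolf count, the sheep count, and the
#' number of grassy patches (the grass-coverage proportion times the patch
#' count), in raw units.
#'
#' @param micro a `wsg_microstate`.
#' @param schema optional schema; defaults to the state components of
#'   [default_wsg_schema()] without parameters.
#' @return an [macro_vector()] with components wolves, sheep, grass.
#' @export
summarize_wsg <- function(micro, schema = NULL) {
  if (is.null(schema)) schema <- default_wsg_schema(parameters = character(0))
  macro_vector(c(nrow(micro$wolves), nrow(micro$sheep), sum(micro$grass_alive)),
               schema)
}

resample_energy <- function(n, survivors, gain) {
  if (nrow(survivors) > 0) {
    survivors[sample.int(nrow(survivors), n, replace = TRUE), 4]
  } else {
    stats::runif(n) * 2 * gain
  }
}

adjust_agents <- function(agents, target, width, height, gain) {
  n <- nrow(agents)
  if (target == n) return(agents)
  if (target < n) {
    keep <- sample.int(n, target)
    return(agents[keep, , drop = FALSE])
  }
  add <- target - n
  extra <- new_agents(add, width, height, resample_energy(add, agents, gain))
  rbind(agents, extra)
}

#' Synthesize a wolf-sheep-grass microstate matching a target macrostate
#'
#' Uniform-random synthesis, appropriate because the model is spatially well
#' mixed: surplus agents are removed uniformly at random; missing agents are
#' added at uniform-random positions with energies resampled from the
#' surviving same-species agents (or from the initialization distribution
#' when none survive); grass patches are flipped alive/dead uniformly at
#' random among eligible patches, with fresh uniform counters on newly bare
#' patches. The result summarizes exactly to the (rounded) target.
#'
#' @param target an [macro_vector()] or named numeric vector with components
#'   wolves, sheep, grass (raw units; rounded to nonnegative integers here).
#' @param seed_micro a `wsg_microstate` used as the continuity seed.
#' @param params a [wsg_params()].
#' @return a `wsg_microstate` with `summarize_wsg()` equal to the target.
#' @export
synthesize_wsg <- function(target, seed_micro, params) {
  v <- if (inherits(target, "abmkf_macro")) target$values else target
  tw <- max(0L, as.integer(round(v[["wolves"]])))
  ts <- max(0L, as.integer(round(v[["sheep"]])))
  tg <- max(0L, as.integer(round(v[["grass"]])))
  w <- params$world_width; h <- params$world_height
  npatch <- w * h
  if (tg > npatch) stop("grass target exceeds patch count")

  wolves <- adjust_agents(seed_micro$wolves, tw, w, h, params$wolf_gain_from_food)
  sheep <- adjust_agents(seed_micro$sheep, ts, w, h, params$sheep_gain_from_food)

  alive <- seed_micro$grass_alive
  counter <- seed_micro$grass_counter
  g <- sum(alive)
  if (tg > g) {
    dead_idx <- which(!alive)
    flip <- if (length(dead_idx) == 1) dead_idx else sample(dead_idx, tg - g)
    alive[flip] <- TRUE
    counter[flip] <- 0L
  } else if (tg < g) {
    alive_idx <- which(alive)
    flip <- if (length(alive_idx) == 1) alive_idx else sample(alive_idx, g - tg)
    alive[flip] <- FALSE
    counter[flip] <- sample.int(params$grass_regrowth_time, length(flip), replace = TRUE)
  }

  structure(list(wolves = wolves, sheep = sheep,
                 grass_alive = alive, grass_counter = counter),
            class = "wsg_microstate")
}

#' Simulate a wolf-sheep-grass macrostate trajectory
#'
#' Convenience wrapper: initialize, step `horizon` times, and collect the
#' macrostate at every time into a data frame.
#'
#' @param params a [wsg_params()].
#' @param horizon number of steps.
#' @param keep_micro if `TRUE` also return the list of microstates.
#' @return a list with `macro` (data frame: time, wolves, sheep, grass) and,
#'   optionally, `micro` (list of microstates).
#' @export
simulate_wsg <- function(params, horizon, keep_micro = FALSE) {
  micro <- init_wsg(params)
  out <- matrix(0, horizon + 1, 3)
  out[1, ] <- summarize_wsg(micro)$values
  micros <- if (keep_micro) vector("list", horizon + 1) else NULL
  if (keep_micro) micros[[1]] <- micro
  for (t in seq_len(horizon)) {
    micro <- step_wsg(micro, params)
    out[t + 1, ] <- summarize_wsg(micro)$values
    if (keep_micro) micros[[t + 1]] <- micro
  }
  macro <- data.frame(time = 0:horizon, wolves = out[, 1], sheep = out[, 2],
                      grass = out[, 3])
  list(macro = macro, micro = micros, final_micro = micro)
}
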