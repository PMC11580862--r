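# Orchestration of the assimilation loop:
#   1. advance the microstate ensemble with the model (each member under its
#      own parameters),
#   2. summarize microstates to transformed macrostates,
#   3. ensemble Kalman update against the macrostate measurement,
#   4. sample a fresh macrostate ensemble from the posterior,
#   5. synthesize a compatible microstate for every posterior sample, seeded
#      from its stable-matched predictive member.
#
# Randomness flows through four named streams (patient, ensemble, filter,
# synthesis), each seeded independently so end-to-end runs are reproducible.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Experiment configuration
#'
#' Bundles the model choice, its parameters, the macrostate schema, the
#' Gaussian prior over the transformed augmented state (observables plus
#' parameter components), and the filter hyperparameters.
#'
#' @param model `"wsg"` or `"viral_min"`.
#' @param params model parameters ([wsg_params()] / [viral_params()]);
#'   defaults per model.
#' @param schema macrostate schema; defaults per model.
#' @param prior_mean,prior_cov prior in transformed space over all schema
#'   components; defaults center the state components on the model's onset
#'   configuration with small spread, and put sd 2 on the percent-scale
#'   parameter components.
#' @param n_ensemble ensemble size (>= 2).
#' @param horizon number of model steps (>= 1).
#' @param observed,R,interval measurement: observed component name(s), noise
#'   variance(s) in transformed units, and the regular measurement interval
#'   (measurements at interval, 2 x interval, ...).
#' @param q_param per-step random-walk variance added to parameter
#'   components of ensemble members (the state components get no added
#'   process noise: the simulator is stochastic already).
#' @param jitter covariance regularization inside the ensemble update.
#' @param synthesis `"uniform"` (wsg), `"simple"` or `"spatial"` (viral).
#' @param quantization a [quantization_config()] for spatial synthesis.
#' @param models optional neighborhood models for spatial synthesis.
#' @return an object of class `abmkf_config`.
#' @export
experiment_config <- function(model = c("wsg", "viral_min"),
                              params = NULL, schema = NULL,
                              prior_mean = NULL, prior_cov = NULL,
                              n_ensemble = 50, horizon = 200,
                              observed = "sheep", R = 0.01,
                              interval = NULL,
                              q_param = 0.01, jitter = 1e-8,
                              synthesis = NULL,
                              quantization = quantization_config(),
                              models = NULL) {
  model <- match.arg(model)
  if (is.null(params))
    params <- if (model == "wsg") wsg_params() else viral_params(n = 25)
  if (is.null(schema))
    schema <- if (model == "wsg") default_wsg_schema() else default_viral_schema()
  if (is.null(synthesis))
    synthesis <- if (model == "wsg") "uniform" else "spatial"
  if (n_ensemble < 2) stop("n_ensemble must be >= 2")
  if (horizon < 1) stop("horizon must be >= 1")
  if (is.null(interval)) interval <- max(1, horizon %/% 10)
  times <- seq(interval, horizon, by = interval)
  d <- length(schema$names)
  if (is.null(prior_mean) || is.null(prior_cov)) {
    pr <- default_prior(model, params, schema)
    if (is.null(prior_mean)) prior_mean <- pr$mean
    if (is.null(prior_cov)) prior_cov <- pr$cov
  }
  stopifnot(length(prior_mean) == d, all(dim(as.matrix(prior_cov)) == d))
  measure <- measurement_spec(observed, R, times)
  if (!all(measure$observed %in% schema$names))
    stop("observed components missing from the schema")
  structure(list(model = model, params = params, schema = schema,
                 prior_mean = stats::setNames(as.numeric(prior_mean), schema$names),
                 prior_cov = as.matrix(prior_cov),
                 n_ensemble = as.integer(n_ensemble),
                 horizon = as.integer(horizon),
                 measure = measure, q_param = q_param, jitter = jitter,
                 synthesis = synthesis, quantization = quantization,
                 models = models),
            class = "abmkf_config")
}

# prior centered on the model's onset configuration (transformed space)
default_prior <- function(model, params, schema) {
  if (model == "wsg") {
    npatch <- params$world_width * params$world_height
    onset <- macro_vector(
      c(params$init_wolves, params$init_sheep,
        params$init_grass_density * npatch,
        100 * params$wolf_reproduce_prob, 100 * params$sheep_reproduce_prob),
      schema)
    sd <- c(0.1, 0.5, 0.5, 2, 2)
  } else {
    nm <- params$n * params$m
    raw <- stats::setNames(numeric(length(schema$names)), schema$names)
    raw["epi_infected"] <- 3
    raw["epi_healthy"] <- nm - 3
    raw["virus_total"] <- 3 * params$init_virus
    raw["endo_normal"] <- nm
    if ("infect_rate_pct" %in% schema$names)
      raw["infect_rate_pct"] <- 100 * params$infect_rate
    onset <- macro_vector(raw, schema)
    sd <- ifelse(schema$is_parameter, 5, 0.2)
  }
  list(mean = to_transformed(onset), cov = diag(sd^2, length(sd)))
}

# model-facing interface used by the driver
model_api <- function(config) {
  schema <- config$schema
  state_names <- schema$names[!schema$is_parameter]
  param_names <- schema$names[schema$is_parameter]
  if (config$model == "wsg") {
    apply_params <- function(raw) {
      p <- config$params
      if ("wolf_reproduce_pct" %in% names(raw))
        p$wolf_reproduce_prob <- clamp(raw[["wolf_reproduce_pct"]] / 100, 0, 1)
      if ("sheep_reproduce_pct" %in% names(raw))
        p$sheep_reproduce_prob <- clamp(raw[["sheep_reproduce_pct"]] / 100, 0, 1)
      p
    }
    npatch <- config$params$world_width * config$params$world_height
    clamp_state <- function(raw_state) {
      # prior draws / posterior samples are clamped to the valid domain
      raw_state["grass"] <- clamp(raw_state[["grass"]], 0, npatch)
      pmax(raw_state, 0)
    }
    list(
      state_names = state_names, param_names = param_names,
      apply_params = apply_params,
      init_member = function(raw_state, p) {
        synthesize_wsg(clamp_state(raw_state), init_wsg(p), p)
      },
      step = function(micro, p) step_wsg(micro, p),
      summarize_raw = function(micro) {
        stats::setNames(summarize_wsg(micro)$values, c("wolves", "sheep", "grass"))
      },
      synthesize = function(target_raw, seed_micro, p) {
        synthesize_wsg(clamp_state(target_raw), seed_micro, p)
      })
  } else {
    apply_params <- function(raw) {
      p <- config$params
      if ("infect_rate_pct" %in% names(raw))
        p$infect_rate <- max(0, raw[["infect_rate_pct"]] / 100)
      p
    }
    synth <- function(target_raw, seed_micro, p) {
      if (config$synthesis == "spatial") {
        spatial_synthesis_viral(target_raw, seed_micro, config$quantization,
                                config$models)
      } else {
        simple_synthesis_viral(target_raw, seed_micro)
      }
    }
    list(
      state_names = state_names, param_names = param_names,
      apply_params = apply_params,
      init_member = function(raw_state, p) {
        nm <- p$n * p$m
        n_seed <- clamp(round(raw_state[["epi_infected"]]), 0, nm)
        synth(raw_state, init_viral(p, n_seed), p)
      },
      step = function(micro, p) step_viral(micro, p),
      summarize_raw = function(micro) {
        sm <- summarize_viral(micro)
        stats::setNames(sm$values, sm$schema$names)
      },
      synthesize = synth)
  }
}

#' Generate a virtual patient
#'
#' Draws the patient's parameters from the prior (rejection-clamped to the
#' valid domain), initializes the microstate in the known onset
#' configuration, simulates to the horizon, and records noisy measurements
#' on the configured schedule. The patient's parameters stay constant over
#' time: process noise applies only to the filter ensemble.
#'
#' @param config an [experiment_config()].
#' @param seed seed of the patient random stream.
#' @param keep_micro if `TRUE`, keep the full microstate trajectory.
#' @return an object of class `virtual_patient` with true parameters (raw
#'   units), raw and transformed macro trajectories, and the measurement
#'   record.
#' @export
make_virtual_patient <- function(config, seed = 1, keep_micro = FALSE) {
  set.seed(seed)
  api <- model_api(config)
  schema <- config$schema
  pidx <- which(schema$is_parameter)
  # rejection sampling of valid parameters from the prior marginal
  ok <- FALSE
  for (attempt in seq_len(100)) {
    draw <- rmvnorm_eig(1, config$prior_mean[pidx],
                        config$prior_cov[pidx, pidx, drop = FALSE])[1, ]
    raw_par <- from_transformed_subset(draw, schema, pidx)
    if (all(raw_par >= 0)) { ok <- TRUE; break }
  }
  if (!ok) stop("could not draw valid parameters from the prior in 100 attempts")
  p <- api$apply_params(raw_par)

  onset_raw <- from_transformed(config$prior_mean, schema)$values
  micro <- api$init_member(onset_raw[!schema$is_parameter], p)

  d <- length(schema$names)
  macro_raw <- matrix(0, config$horizon + 1, d,
                      dimnames = list(NULL, schema$names))
  micros <- if (keep_micro) vector("list", config$horizon + 1) else NULL
  fill <- function(t, micro) {
    vals <- c(api$summarize_raw(micro), raw_par)
    macro_raw[t, ] <<- vals[schema$names]
  }
  fill(1, micro)
  if (keep_micro) micros[[1]] <- micro
  for (t in seq_len(config$horizon)) {
    micro <- api$step(micro, p)
    fill(t + 1, micro)
    if (keep_micro) micros[[t + 1]] <- micro
  }
  macro_tr <- t(apply(macro_raw, 1, function(v)
    to_transformed(macro_vector(v, schema))))
  colnames(macro_tr) <- schema$names

  times <- config$measure$times
  H <- selection_matrix(config$measure$observed, schema$names)
  Y <- matrix(0, length(times), length(config$measure$observed),
              dimnames = list(NULL, config$measure$observed))
  for (ti in seq_along(times)) {
    truth <- macro_tr[times[ti] + 1, ]
    Y[ti, ] <- as.numeric(H %*% truth) +
      stats::rnorm(nrow(H), 0, sqrt(config$measure$R))
  }
  structure(list(true_params = raw_par, macro_raw = macro_raw,
                 macro_transformed = macro_tr,
                 measurements = list(times = times, Y = Y),
                 micro = micros, final_micro = micro),
            class = "virtual_patient")
}

from_transformed_subset <- function(v, schema, idx) {
  out <- mapply(function(tr, x) invert_transform(tr, x),
                schema$transforms[idx], as.numeric(v))
  names(out) <- schema$names[idx]
  out
}

#' Run the assimilation loop against a virtual patient
#'
#' Initializes a microstate ensemble from prior draws (each draw realized
#' through the model's init/synthesize path), then alternates model
#' advancement with ensemble Kalman updates at the measurement times,
#' pairing predictive members with posterior samples by stable matching and
#' synthesizing a compatible microstate for every posterior sample. Records
#' the predictive belief and the surprisal of the true transformed
#' macrostate at every step (pre-update at measurement times), and the
#' posterior belief and surprisal at measurement times.
#'
#' @param config an [experiment_config()].
#' @param patient a [make_virtual_patient()] result.
#' @param seed base seed from which the ensemble, filter, and synthesis
#'   streams are derived.
#' @param assimilate set `FALSE` for the pure-forecast baseline (no
#'   updates, no synthesis).
#' @return an object of class `abmkf_result` with elements `times`,
#'   `surprisal` (predictive series), `post_times`, `surprisal_post`,
#'   `pred_mean`, `pred_sd`, `post_beliefs`, and the final `ensemble`.
#' @export
run_abmkf <- function(config, patient, seed = 1, assimilate = TRUE) {
  api <- model_api(config)
  schema <- config$schema
  d <- length(schema$names)
  n <- config$n_ensemble
  pidx <- which(schema$is_parameter)
  sidx <- which(!schema$is_parameter)
  seed_ens <- mix_seed(seed, 11); seed_filter <- mix_seed(seed, 12)
  seed_synth <- mix_seed(seed, 13)

  set.seed(seed_ens)
  draws <- rmvnorm_eig(n, config$prior_mean, config$prior_cov)
  micros <- vector("list", n)
  param_mat <- draws[, pidx, drop = FALSE]
  for (i in seq_len(n)) {
    raw <- from_transformed(draws[i, ], schema)$values
    p_i <- api$apply_params(raw[pidx])
    micros[[i]] <- api$init_member(raw[sidx], p_i)
  }

  ens_matrix <- function() {
    X <- matrix(0, n, d, dimnames = list(NULL, schema$names))
    for (i in seq_len(n)) {
      raw <- stats::setNames(numeric(d), schema$names)
      raw[sidx] <- api$summarize_raw(micros[[i]])[schema$names[sidx]]
      tr_state <- to_transformed(macro_vector(raw, schema))
      X[i, sidx] <- tr_state[sidx]
      X[i, pidx] <- param_mat[i, ]
    }
    X
  }

  horizon <- config$horizon
  pred_mean <- matrix(0, horizon + 1, d, dimnames = list(NULL, schema$names))
  pred_sd <- pred_mean
  surprisal <- numeric(horizon + 1)
  times_meas <- if (assimilate) config$measure$times else integer(0)
  surprisal_post <- stats::setNames(numeric(length(times_meas)),
                                    as.character(times_meas))
  post_beliefs <- list()

  X <- ens_matrix()
  record <- function(t, X) {
    bel <- fit_gaussian(X)
    pred_mean[t + 1, ] <<- bel$mean
    pred_sd[t + 1, ] <<- sqrt(pmax(diag(bel$cov), 0))
    surprisal[t + 1] <<- gaussian_surprisal(
      gaussian_belief(bel$mean, bel$cov + diag(config$jitter, d)),
      patient$macro_transformed[t + 1, ])
  }
  record(0, X)

  mi <- 1L
  for (t in seq_len(horizon)) {
    set.seed(mix_seed(seed_ens, t))
    for (i in seq_len(n)) {
      p_i <- api$apply_params(from_transformed_subset(param_mat[i, ], schema, pidx))
      micros[[i]] <- api$step(micros[[i]], p_i)
    }
    param_mat <- add_parameter_process_noise(
      cbind(param_mat), config$q_param, rep(TRUE, length(pidx)))
    X <- ens_matrix()
    record(t, X)

    if (t %in% times_meas) {
      set.seed(mix_seed(seed_filter, t))
      y <- patient$measurements$Y[match(t, patient$measurements$times), ]
      upd <- enkf_update(X, config$measure, y, jitter = config$jitter)
      surprisal_post[as.character(t)] <- gaussian_surprisal(
        upd$belief, patient$macro_transformed[t + 1, ])
      post_beliefs[[as.character(t)]] <- upd$belief

      set.seed(mix_seed(seed_synth, t))
      pairing <- pair_ensembles(X, upd$ensemble)
      new_micros <- vector("list", n)
      new_params <- matrix(0, n, length(pidx),
                           dimnames = list(NULL, schema$names[pidx]))
      for (j in seq_len(n)) {
        post_raw <- from_transformed(upd$ensemble[j, ], schema)$values
        p_j <- api$apply_params(post_raw[pidx])
        new_micros[[j]] <- api$synthesize(post_raw[sidx],
                                          micros[[pairing[j]]], p_j)
        new_params[j, ] <- upd$ensemble[j, pidx]
      }
      micros <- new_micros
      param_mat <- new_params
      X <- ens_matrix()
      mi <- mi + 1L
    }
  }

  structure(list(times = 0:horizon, surprisal = surprisal,
                 post_times = times_meas, surprisal_post = surprisal_post,
                 pred_mean = pred_mean, pred_sd = pred_sd,
                 post_beliefs = post_beliefs, ensemble = X),
            class = "abmkf_result")
}
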