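# Ensemble Kalman filter on transformed macrostates, with the exact linear
# Kalman filter available as a test oracle.
#
# The EnKF variant is the classic perturbed-observation (stochastic) form:
# each ensemble member is updated with an independently perturbed copy of
# the observation using the sample-covariance gain. After every update a
# Gaussian is fitted to the updated members and a fresh ensemble is drawn
# from it, so the filter hands a clean posterior sample to microstate
# synthesis.

#' Gaussian belief
#'
#' Mean / covariance pair representing a filtered macrostate distribution.
#' The covariance is symmetrized on construction; it must be symmetric to
#' within 1e-10 and have eigenvalues >= -1e-10.
#'
#' @param mean numeric vector.
#' @param cov square covariance matrix conformable with `mean`.
#' @return an object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  d <- length(mean)
  stopifnot(nrow(cov) == d, ncol(cov) == d)
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance is not symmetric")
  cov <- sym_part(cov)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(abs(ev))))
    stop("covariance has a substantially negative eigenvalue")
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("Gaussian belief, dimension", length(x$mean), "\n")
  cat("mean:", format(x$mean, digits = 4), "\n")
  invisible(x)
}

#' Kalman filter prediction step (linear oracle)
#'
#' Exact moment propagation through a linear-Gaussian model:
#' m <- A m, P <- A P A' + Q. Used as the closed-form oracle against which
#' the ensemble filter is validated.
#'
#' @param belief a [gaussian_belief()].
#' @param A linear dynamics matrix.
#' @param Q process-noise covariance.
#' @return a [gaussian_belief()].
#' @export
kf_predict <- function(belief, A, Q) {
  A <- as.matrix(A); Q <- as.matrix(Q)
  gaussian_belief(A %*% belief$mean, A %*% belief$cov %*% t(A) + Q)
}

#' Kalman filter measurement update (linear oracle)
#'
#' Exact conjugate update for a linear observation y = H x + e, e ~ N(0, R):
#' K = P H' (H P H' + R)^-1, m <- m + K (y - H m), P <- (I - K H) P.
#'
#' @param belief a [gaussian_belief()].
#' @param H observation (selection) matrix.
#' @param R observation-noise covariance (positive definite).
#' @param y observed vector.
#' @return the posterior [gaussian_belief()].
#' @export
kf_update <- function(belief, H, R, y) {
  H <- as.matrix(H); R <- as.matrix(R)
  P <- belief$cov
  S <- H %*% P %*% t(H) + R
  Sc <- tryCatch(chol(sym_part(S)), error = function(e) NULL)
  if (is.null(Sc)) stop("singular innovation covariance")
  K <- t(backsolve(Sc, forwardsolve(t(Sc), H %*% P)))
  m <- belief$mean + as.numeric(K %*% (y - H %*% belief$mean))
  P_post <- (diag(length(belief$mean)) - K %*% H) %*% P
  gaussian_belief(m, sym_part(P_post))
}

#' Measurement specification
#'
#' Which macrostate components are observed, with one diagonal noise
#' variance per observed component (in *transformed* units), and the
#' measurement schedule.
#'
#' @param observed character vector of observed component names (nonempty).
#' @param R numeric vector of noise variances (> 0), recycled to the length
#'   of `observed`.
#' @param times integer vector of measurement times (may be empty).
#' @return an object of class `measurement_spec`.
#' @export
measurement_spec <- function(observed, R, times = integer(0)) {
  observed <- as.character(observed)
  if (!length(observed)) stop("observed must be nonempty")
  R <- rep_len(as.numeric(R), length(observed))
  if (any(R <= 0)) stop("measurement variances must be > 0")
  structure(list(observed = observed, R = stats::setNames(R, observed),
                 times = as.integer(times)),
            class = "measurement_spec")
}

# 0/1 selection matrix picking `observed` rows out of `all_names`
selection_matrix <- function(observed, all_names) {
  idx <- match(observed, all_names)
  if (anyNA(idx)) stop("unknown observed component: ",
                       paste(observed[is.na(idx)], collapse = ", "))
  H <- matrix(0, length(observed), length(all_names))
  H[cbind(seq_along(idx), idx)] <- 1
  colnames(H) <- all_names
  H
}

#' Perturbed-observation ensemble Kalman update
#'
#' Fits a sample Gaussian (denominator n-1) to the predictive ensemble,
#' updates every member with an independently perturbed observation
#' y + eta_i, eta_i ~ N(0, R), using the sample-covariance gain, fits a
#' Gaussian to the updated members, and draws a fresh same-size ensemble
#' from that posterior (jitter `jitter * I` added before sampling, guarding
#' against the degenerate ensembles that arise near absorbing states).
#'
#' @param ens n x d matrix of transformed macrostate members (n >= 2),
#'   columns named by component.
#' @param spec a [measurement_spec()] (or an observation matrix `H`).
#' @param y observed vector (transformed units).
#' @param jitter diagonal regularization added before resampling.
#' @return list with `belief` (posterior [gaussian_belief()]) and `ensemble`
#'   (fresh n x d posterior sample).
#' @export
enkf_update <- function(ens, spec, y, jitter = 1e-8) {
  ens <- as.matrix(ens)
  n <- nrow(ens); d <- ncol(ens)
  if (n < 2) stop("ensemble must have at least 2 members")
  H <- if (inherits(spec, "measurement_spec")) {
    selection_matrix(spec$observed, colnames(ens))
  } else as.matrix(spec)
  R <- if (inherits(spec, "measurement_spec")) diag(spec$R, length(spec$R)) else
    stop("enkf_update requires a measurement_spec")
  P <- stats::cov(ens)
  S <- H %*% P %*% t(H) + R
  K <- P %*% t(H) %*% solve(sym_part(S))
  eta <- rmvnorm_eig(n, rep(0, nrow(H)), R)
  innov <- matrix(y, n, nrow(H), byrow = TRUE) + eta - ens %*% t(H)
  upd <- ens + innov %*% t(K)
  post <- fit_gaussian(upd)
  post_cov <- post$cov + diag(jitter, d)
  belief <- gaussian_belief(post$mean, post_cov)
  fresh <- rmvnorm_eig(n, belief$mean, belief$cov)
  colnames(fresh) <- colnames(ens)
  list(belief = belief, ensemble = fresh)
}

#' Add process noise to parameter components only
#'
#' The simulator supplies its own stochasticity for the state components, so
#' random-walk process noise is injected only into the parameter components
#' of each ensemble member (independent N(0, Q) increments).
#'
#' @param ens n x d ensemble matrix with named columns.
#' @param q_param named numeric vector of per-step variances, indexed by
#'   parameter-component name (or a scalar applied to all of `is_parameter`).
#' @param is_parameter logical vector over columns of `ens`.
#' @return the perturbed ensemble.
#' @export
add_parameter_process_noise <- function(ens, q_param, is_parameter) {
  ens <- as.matrix(ens)
  stopifnot(length(is_parameter) == ncol(ens))
  idx <- which(is_parameter)
  if (!length(idx)) return(ens)
  q <- if (length(q_param) == 1 && is.null(names(q_param))) {
    rep(as.numeric(q_param), length(idx))
  } else {
    qq <- as.numeric(q_param[colnames(ens)[idx]])
    if (anyNA(qq)) stop("q_param missing entries for some parameter components")
    qq
  }
  for (k in seq_along(idx)) {
    if (q[k] > 0)
      ens[, idx[k]] <- ens[, idx[k]] + stats::rnorm(nrow(ens), 0, sqrt(q[k]))
  }
  ens
}
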