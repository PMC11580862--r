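test_that("linear prediction matches brute-force moment propagation", {
  b <- gaussian_belief(c(1, -1), matrix(c(2, 0.5, 0.5, 1), 2))

  expect_equal(kf_predict(b, diag(2), matrix(0, 2, 2)), b)
  pq <- kf_predict(b, diag(2), diag(0.3, 2))
  expect_equal(pq$cov, b$cov + diag(0.3, 2))

  set.seed(1)
  A <- matrix(c(0.9, 0.2, -0.3, 1.1), 2)
  Q <- crossprod(matrix(stats::rnorm(4), 2)) / 2
  pred <- kf_predict(b, A, Q)
  x <- abmkf:::rmvnorm_eig(1e6, b$mean, b$cov)
  y <- x %*% t(A) + abmkf:::rmvnorm_eig(1e6, c(0, 0), Q)
  expect_equal(colMeans(y), pred$mean, tolerance = 0.02)
  expect_lt(norm(stats::cov(y) - pred$cov, "F") / norm(pred$cov, "F"), 0.02)
})

test_that("scalar and limiting Kalman updates have their closed forms", {
  b <- gaussian_belief(0, matrix(1))
  post <- kf_update(b, matrix(1), matrix(1), 2)
  expect_equal(post$mean, 1, tolerance = 1e-12)
  expect_equal(post$cov[1, 1], 0.5, tolerance = 1e-12)

  # uninformative measurement leaves the prior untouched
  post2 <- kf_update(b, matrix(1), matrix(1e12), 2)
  expect_equal(post2$mean, b$mean, tolerance = 1e-6)
  expect_equal(post2$cov, b$cov, tolerance = 1e-6)
})

test_that("partial 2D update matches grid-integration Bayes", {
  m <- c(1, 2); P <- matrix(c(1.5, 0.6, 0.6, 1.0), 2)
  H <- matrix(c(1, 0), 1, 2); R <- matrix(0.4); y <- 2.5
  post <- kf_update(gaussian_belief(m, P), H, R, y)

  gx <- seq(m[1] - 6, m[1] + 6, length.out = 401)
  gy <- seq(m[2] - 6, m[2] + 6, length.out = 401)
  Pi <- solve(P)
  grid <- expand.grid(x = gx, y = gy)
  dx <- cbind(grid$x - m[1], grid$y - m[2])
  logp <- -0.5 * rowSums((dx %*% Pi) * dx) - 0.5 * (grid$x - y)^2 / R[1, 1]
  w <- exp(logp - max(logp)); w <- w / sum(w)
  mu <- c(sum(w * grid$x), sum(w * grid$y))
  cx <- cbind(grid$x - mu[1], grid$y - mu[2])
  Sg <- t(cx) %*% (cx * w)
  expect_equal(post$mean, mu, tolerance = 1e-3)
  expect_equal(post$cov, unname(Sg), tolerance = 1e-3)
})

test_that("posterior covariance contracts in the fully observed case", {
  set.seed(2)
  for (rep in 1:10) {
    P <- crossprod(matrix(stats::rnorm(9), 3)) + 0.1 * diag(3)
    b <- gaussian_belief(stats::rnorm(3), P)
    post <- kf_update(b, diag(3), diag(0.5, 3), stats::rnorm(3))
    ev_prior <- sort(eigen(b$cov, symmetric = TRUE, only.values = TRUE)$values)
    ev_post <- sort(eigen(post$cov, symmetric = TRUE, only.values = TRUE)$values)
    expect_true(all(ev_post <= ev_prior + 1e-10))
  }
})

test_that("ensemble update handles degenerate and exact-measurement limits", {
  # zero spread: gain 0, members unchanged up to jitter
  ens <- matrix(rep(c(1, 2, 3), each = 20), 20, 3)
  colnames(ens) <- c("a", "b", "c")
  spec <- measurement_spec("a", 1)
  set.seed(3)
  up <- enkf_update(ens, spec, 10)
  expect_equal(up$belief$mean, c(1, 2, 3), tolerance = 1e-3)

  # observing everything with tiny noise pins the posterior to y
  set.seed(4)
  ens2 <- abmkf:::rmvnorm_eig(200, c(0, 0, 0), diag(3))
  colnames(ens2) <- c("a", "b", "c")
  y <- c(1.7, -0.3, 0.9)
  up2 <- enkf_update(ens2, measurement_spec(c("a", "b", "c"), 1e-10), y)
  expect_equal(up2$belief$mean, y, tolerance = 1e-3)

  expect_error(enkf_update(ens2[1, , drop = FALSE], spec, 1), "at least 2")
})

test_that("ensemble update converges to the exact Kalman update", {
  m0 <- c(1, -2, 3)
  set.seed(5)
  P0 <- crossprod(matrix(stats::rnorm(9), 3)) + diag(3)
  spec <- measurement_spec(c("a", "b"), c(0.5, 0.25))
  H <- abmkf:::selection_matrix(c("a", "b"), c("a", "b", "c"))
  y <- c(2, -1)
  oracle <- kf_update(gaussian_belief(m0, P0), H, diag(c(0.5, 0.25)), y)
  err <- vapply(c(100, 1000, 5000), function(n) {
    set.seed(n)
    ens <- abmkf:::rmvnorm_eig(n, m0, P0)
    colnames(ens) <- c("a", "b", "c")
    up <- enkf_update(ens, spec, y)
    sqrt(sum((up$belief$mean - oracle$mean)^2)) +
      norm(up$belief$cov - oracle$cov, "F")
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("process noise touches only parameter components", {
  set.seed(6)
  ens <- matrix(stats::rnorm(400), 100, 4)
  colnames(ens) <- c("s1", "s2", "p1", "p2")
  is_par <- c(FALSE, FALSE, TRUE, TRUE)

  expect_identical(add_parameter_process_noise(ens, 0, is_par), ens)

  out <- add_parameter_process_noise(ens, 0.5, is_par)
  expect_identical(out[, 1:2], ens[, 1:2])

  # empirical variance of the increments matches Q
  big <- matrix(0, 1e4, 4, dimnames = list(NULL, colnames(ens)))
  inc <- add_parameter_process_noise(big, c(p1 = 0.25, p2 = 1), is_par)
  expect_equal(stats::var(inc[, "p1"]), 0.25, tolerance = 0.05)
  expect_equal(stats::var(inc[, "p2"]), 1, tolerance = 0.05)
  expect_true(all(inc[, 1:2] == 0))
})
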