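test_that("stable matching pairs nearby ensembles without blocking pairs", {
  set.seed(1)
  x <- matrix(stats::rnorm(12), 6, 2)
  expect_equal(pair_ensembles(x, x), 1:6)

  expect_error(pair_ensembles(x, x[1:3, ]), "equal sizes")

  # exhaustively verified stability for n <= 6
  for (trial in 1:30) {
    n <- sample(2:6, 1)
    pred <- matrix(stats::rnorm(2 * n), n, 2)
    post <- matrix(stats::rnorm(2 * n), n, 2)
    pairing <- pair_ensembles(pred, post)
    expect_true(all(sort(pairing) == 1:n))
    expect_false(has_blocking_pair(pred, post, pairing))
  }
})

test_that("one-hot encoding maps categories to basis vectors and back", {
  set.seed(2)
  g <- matrix(sample.int(5, 30, replace = TRUE), 5, 6)
  f <- one_hot_encode(g, k = 5)
  # a healthy (code 1) site becomes e1
  i <- which(g == 1)[1]
  expect_equal(matrix(f, 30, 5)[i, ], c(1, 0, 0, 0, 0))
  expect_identical(one_hot_decode(f), g)
  expect_equal(apply(f, 3, sum), tabulate(g, 5))
  expect_error(one_hot_encode(matrix(6, 1, 1), k = 5), "outside")
})

test_that("one-hot rescaling moves the counts while scaling sites", {
  set.seed(3)
  g <- matrix(sample.int(3, 16, replace = TRUE, prob = c(0.5, 0.3, 0.2)), 4, 4)
  f <- one_hot_encode(g, k = 3)
  old <- tabulate(g, 3)

  expect_equal(rescale_onehot(f, old, old), f)

  new <- old + c(-2, 2, 0)
  r <- rescale_onehot(f, old, new)
  expect_equal(apply(r, 3, sum), new, tolerance = 1e-9)
  expect_equal(r[, , 2], f[, , 2] * (new[2] / old[2]))

  expect_error(rescale_onehot(f, old, old + 1), "equal totals")

  # a category absent from the field gets its mass spread uniformly
  g2 <- matrix(1L, 2, 2)
  f2 <- one_hot_encode(g2, k = 2)
  r2 <- rescale_onehot(f2, c(4, 0), c(3, 1))
  expect_equal(r2[, , 2], matrix(0.25, 2, 2))
  expect_equal(apply(r2, 3, sum), c(3, 1), tolerance = 1e-9)
})

test_that("molecular rescaling preserves spatial correlation exactly", {
  set.seed(4)
  f <- matrix(stats::rexp(100), 10, 10)
  expect_equal(rescale_molecular(f, sum(f)), f)
  expect_equal(sum(rescale_molecular(f, 37.5)), 37.5, tolerance = 1e-9)
  expect_equal(stats::cor(as.vector(f), as.vector(rescale_molecular(f, 37.5))), 1)
  expect_true(all(rescale_molecular(f, 0) == 0))
  z <- matrix(0, 4, 4)
  expect_equal(rescale_molecular(z, 8), matrix(0.5, 4, 4))
  expect_error(rescale_molecular(f, -1), "nonnegative")
})

test_that("quantization fixes one-hot inputs and solves the 1x2 case", {
  cfg <- quantization_config(lambda1 = 1, lambda2 = 0, lambda3 = 0)
  set.seed(5)
  g <- matrix(sample.int(5, 36, replace = TRUE), 6, 6)
  f <- one_hot_encode(g, k = 5)
  expect_identical(quantize_error_diffuse(f, tabulate(g, 5), cfg), g)

  # the L1-minimal feasible labeling of a 1x2 lattice
  s <- array(0, c(1, 2, 5))
  s[1, 1, 1:2] <- c(0.6, 0.4)
  s[1, 2, 1:2] <- c(0.4, 0.6)
  lab <- quantize_error_diffuse(s, c(1, 1, 0, 0, 0), cfg)
  expect_equal(as.vector(lab), c(1, 2))

  expect_error(quantize_error_diffuse(s, c(2, 1, 0, 0, 0), cfg), "infeasible")
})

test_that("quantization returns exact target counts on random fields", {
  cfg <- quantization_config()
  set.seed(6)
  for (trial in 1:100) {
    k <- sample(c(3, 5), 1)
    f <- array(stats::runif(25 * k), c(5, 5, k))
    counts <- tabulate(sample.int(k, 25, replace = TRUE), nbins = k)
    lab <- quantize_error_diffuse(f, counts, cfg)
    expect_equal(tabulate(lab, k), counts)
  }
})

test_that("error diffusion conserves total vector mass mid-pass", {
  set.seed(7)
  f <- array(stats::runif(8 * 8 * 3), c(8, 8, 3))
  target <- round_largest_remainder(apply(f, 3, sum), total = 64)
  lab <- quantize_error_diffuse(f, target, quantization_config(lambda1 = 1),
                                trace = TRUE)
  tr <- attr(lab, "trace")
  m0 <- apply(f, 3, sum)
  for (row in seq_len(nrow(tr)))
    expect_equal(tr[row, ], m0, tolerance = 1e-9)
})

test_that("neighborhood model frequencies match direct counting", {
  g <- matrix(c(1L, 1L, 2L, 1L), 2, 2)
  model <- build_neighborhood_model(list(g))
  expect_equal(model$total, 4L)
  # the site (1,1) configuration, counted by hand from the padded lattice
  cats9 <- abmkf:::local_cats9(g, 1, 1)
  nlp <- neighborhood_neglogp(model, cats9)
  expect_equal(nlp, -log((1 + 1) / (4 + model$n_distinct + 1)), tolerance = 1e-12)
  # unseen configurations stay finite through smoothing
  expect_true(is.finite(neighborhood_neglogp(model, rep(2L, 9))))
  # a uniform training grid gives every interior site the same query value
  gu <- matrix(1L, 4, 4)
  mu <- build_neighborhood_model(list(gu))
  q1 <- neighborhood_neglogp(mu, abmkf:::local_cats9(gu, 2, 2))
  q2 <- neighborhood_neglogp(mu, abmkf:::local_cats9(gu, 3, 3))
  expect_equal(q1, q2)
  expect_error(build_neighborhood_model(list()), "empty")
})

test_that("simple viral synthesis relabels the minimum number of sites", {
  p <- viral_params(n = 12)
  set.seed(8)
  seed_micro <- make_hotspot_micro(p, steps = 40, min_infected = 3)
  sm <- summarize_viral(seed_micro)$values

  fixed <- simple_synthesis_viral(sm, seed_micro)
  expect_identical(fixed$epithelium, seed_micro$epithelium)

  tv <- sm
  tv["epi_infected"] <- tv["epi_infected"] + 1
  tv["epi_healthy"] <- tv["epi_healthy"] - 1
  one <- simple_synthesis_viral(tv, seed_micro)
  expect_equal(sum(one$epithelium != seed_micro$epithelium), 1)

  # relabeled sites = half the L1 distance between count vectors
  tv2 <- perturb_viral_target(seed_micro)
  out <- simple_synthesis_viral(tv2, seed_micro)
  l1 <- sum(abs(tabulate(out$epithelium, 5) - tabulate(seed_micro$epithelium, 5)))
  expect_equal(sum(out$epithelium != seed_micro$epithelium), l1 / 2)
})

test_that("both viral synthesis routes are macrostate-exact", {
  p <- viral_params(n = 12)
  set.seed(9)
  seed_micro <- make_hotspot_micro(p, steps = 40, min_infected = 3)
  for (trial in 1:25) {
    tv <- perturb_viral_target(seed_micro)
    for (synth in list(simple_synthesis_viral,
                       function(t, s) spatial_synthesis_viral(t, s))) {
      out <- synth(tv, seed_micro)
      got <- summarize_viral(out)$values
      expect_equal(unname(got[5:14]), unname(round(tv[5:14])))
      expect_equal(unname(got[1:4]), unname(tv[1:4]), tolerance = 1e-9)
    }
  }
})

test_that("identity-target spatial synthesis is a fixed point", {
  p <- viral_params(n = 12)
  set.seed(10)
  seed_micro <- make_hotspot_micro(p, steps = 40, min_infected = 3)
  sm <- summarize_viral(seed_micro)$values
  out <- spatial_synthesis_viral(sm, seed_micro,
                                 quantization_config(lambda1 = 1, lambda2 = 0,
                                                     lambda3 = 0))
  expect_identical(out$epithelium, seed_micro$epithelium)
  expect_identical(out$endothelium, seed_micro$endothelium)
  expect_equal(out$virus, seed_micro$virus, tolerance = 1e-12)
})
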