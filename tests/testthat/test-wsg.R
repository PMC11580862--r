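test_that("initialization respects boundary densities and counts", {
  p <- wsg_params(init_grass_density = 1, init_wolves = 0, init_sheep = 5,
                  world_width = 10, world_height = 10)
  set.seed(1)
  m <- init_wsg(p)
  expect_true(all(m$grass_alive))
  expect_true(all(m$grass_counter == 0L))
  expect_equal(nrow(m$wolves), 0)
  expect_equal(nrow(m$sheep), 5)
  expect_true(all(m$sheep[, "x"] >= 0 & m$sheep[, "x"] < 10))
  expect_true(all(m$sheep[, "energy"] >= 0 &
                    m$sheep[, "energy"] <= 2 * p$sheep_gain_from_food))
})

test_that("initial grass coverage follows the binomial model", {
  p <- wsg_params(init_grass_density = 0.5, world_width = 255, world_height = 255,
                  init_wolves = 0, init_sheep = 0)
  set.seed(42)
  m <- init_wsg(p)
  frac <- mean(m$grass_alive)
  sigma <- sqrt(0.5 * 0.5 / (255 * 255))
  expect_lt(abs(frac - 0.5), 3 * sigma)
  # bare patches carry uniform counters in [1, regrowth]
  expect_true(all(m$grass_counter[!m$grass_alive] >= 1))
  expect_true(all(m$grass_counter[!m$grass_alive] <= p$grass_regrowth_time))
})

test_that("grass regrows when its counter reaches zero", {
  p <- wsg_params(init_wolves = 0, init_sheep = 0, world_width = 1,
                  world_height = 1, init_grass_density = 0)
  m <- init_wsg(p)
  m$grass_counter[1, 1] <- 1L
  m2 <- step_wsg(m, p)
  expect_true(m2$grass_alive[1, 1])
  expect_equal(m2$grass_counter[1, 1], 0L)
})

test_that("reproduction splits energy between parent and child", {
  p <- wsg_params(init_wolves = 0, init_sheep = 1, sheep_reproduce_prob = 1,
                  world_width = 9, world_height = 9, init_grass_density = 0)
  set.seed(3)
  m <- init_wsg(p)
  e0 <- as.numeric(m$sheep[1, "energy"])
  m2 <- step_wsg(m, p)
  expect_equal(nrow(m2$sheep), 2)
  # total energy after the step: e0 - 1 (movement), then split exactly
  expect_equal(sum(m2$sheep[, "energy"]), e0 - 1, tolerance = 1e-12)
  expect_equal(m2$sheep[1, "energy"], m2$sheep[2, "energy"], tolerance = 1e-12)
})

test_that("a wolf sharing a patch with a sheep eats it", {
  # 1x1 world forces co-location whatever the random walk does
  p <- wsg_params(init_wolves = 1, init_sheep = 1, wolf_reproduce_prob = 0,
                  sheep_reproduce_prob = 0, world_width = 1, world_height = 1,
                  init_grass_density = 0)
  set.seed(4)
  m <- init_wsg(p)
  e0 <- m$wolves[1, "energy"]
  m2 <- step_wsg(m, p)
  expect_equal(nrow(m2$sheep), 0)
  expect_equal(m2$wolves[1, "energy"], e0 - 1 + p$wolf_gain_from_food,
               tolerance = 1e-12)
})

test_that("grass bookkeeping and reproducibility invariants hold over a run", {
  p <- small_wsg_params()
  set.seed(7)
  m <- init_wsg(p)
  npatch <- p$world_width * p$world_height
  for (t in 1:50) {
    m <- step_wsg(m, p)
    expect_equal(sum(m$grass_alive) + sum(m$grass_counter > 0), npatch)
    expect_true(all(m$grass_counter[m$grass_alive] == 0L))
    if (nrow(m$wolves)) expect_true(all(m$wolves[, "energy"] >= 0))
  }
  # bit-for-bit reproducibility under a fixed seed
  run <- function() {
    set.seed(99)
    mm <- init_wsg(p)
    for (t in 1:20) mm <- step_wsg(mm, p)
    mm
  }
  expect_identical(run(), run())
})

test_that("without food or reproduction the sheep population only declines", {
  p <- wsg_params(init_wolves = 0, init_sheep = 40, sheep_reproduce_prob = 0,
                  wolf_reproduce_prob = 0, world_width = 10, world_height = 10,
                  init_grass_density = 0)
  set.seed(6)
  m <- init_wsg(p)
  # keep the world grassless so sheep can only starve
  m$grass_counter[] <- p$grass_regrowth_time
  counts <- nrow(m$sheep)
  for (t in 1:30) {
    m$grass_counter[] <- p$grass_regrowth_time
    m$grass_alive[] <- FALSE
    m <- step_wsg(m, p)
    counts <- c(counts, nrow(m$sheep))
  }
  expect_true(all(diff(counts) <= 0))
})

test_that("summarization counts agents and grassy patches", {
  p <- wsg_params(init_wolves = 3, init_sheep = 5, world_width = 4,
                  world_height = 4, init_grass_density = 0)
  set.seed(5)
  m <- init_wsg(p)
  m$grass_alive[c(1, 5, 9, 13, 2, 6, 10)] <- TRUE
  m$grass_counter[c(1, 5, 9, 13, 2, 6, 10)] <- 0L
  expect_equal(unname(summarize_wsg(m)$values), c(3, 5, 7))
})

test_that("uniform synthesis hits the target macrostate exactly", {
  p <- small_wsg_params()
  set.seed(11)
  seed_micro <- init_wsg(p)
  for (t in 1:30) seed_micro <- step_wsg(seed_micro, p)

  # fixed point: identical state back
  tgt <- summarize_wsg(seed_micro)
  expect_identical(synthesize_wsg(tgt, seed_micro, p), seed_micro)

  # wolf extinction target empties the wolf collection
  v <- tgt$values; v["wolves"] <- 0
  expect_equal(nrow(synthesize_wsg(v, seed_micro, p)$wolves), 0)

  # grass target above the patch count is infeasible
  v2 <- tgt$values; v2["grass"] <- p$world_width * p$world_height + 1
  expect_error(synthesize_wsg(v2, seed_micro, p), "exceeds patch count")

  # random valid targets: summarize o synthesize is the identity, and new
  # agents take energies from the survivors' empirical distribution
  npatch <- p$world_width * p$world_height
  for (trial in 1:100) {
    target <- c(wolves = sample(0:40, 1), sheep = sample(0:80, 1),
                grass = sample(0:npatch, 1))
    out <- synthesize_wsg(target, seed_micro, p)
    expect_equal(unname(summarize_wsg(out)$values), unname(target))
  }
})
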