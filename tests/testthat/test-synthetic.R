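test_that("zero noise reproduces the simulation exactly at sampling times", {
  sim <- nh3_sim()
  obs <- generate_observations(sim$params, sim$schedule,
                               noise_model(cv = 0, effective_counts = Inf,
                                           floor = 0),
                               seed = 5, sim = sim)
  expect_equal(obs$concentrations$value, obs$concentrations$truth)
  expect_equal(obs$community$abundance, obs$community$truth)
  ts <- sim$timeseries
  ac0 <- obs$concentrations[obs$concentrations$acid == "ac", ]
  i <- match(ac0$time, ts$time)
  expect_equal(ac0$value, ts$S_ac[i], tolerance = 1e-12)
})

test_that("identical seeds give identical observation sets", {
  sim <- nh3_sim()
  o1 <- generate_observations(sim$params, sim$schedule, seed = 42, sim = sim)
  o2 <- generate_observations(sim$params, sim$schedule, seed = 42, sim = sim)
  expect_identical(o1$concentrations, o2$concentrations)
  expect_identical(o1$community, o2$community)
  o3 <- generate_observations(sim$params, sim$schedule, seed = 43, sim = sim)
  expect_false(identical(o1$concentrations$value, o3$concentrations$value))
})

test_that("multiplicative noise is median-centred on the truth", {
  sim <- nh3_sim()
  times <- c(10, 30, 50)
  reps <- 100
  vals <- sapply(seq_len(reps), function(k) {
    o <- generate_observations(sim$params, sim$schedule,
                               noise_model(cv = 0.07, floor = 0),
                               seed = 1000 + k, times = times, sim = sim)
    o$concentrations$value[o$concentrations$acid == "ac"]
  })
  truth <- approx(sim$timeseries$time, sim$timeseries$S_ac, times)$y
  for (i in seq_along(times)) {
    se <- sd(vals[i, ]) / sqrt(reps)
    expect_lt(abs(mean(vals[i, ]) - truth[i]), 2 * se + 0.0025 * truth[i])
  }
})

test_that("censoring never produces values below the floor and is reported", {
  sim <- nh3_sim()
  obs <- generate_observations(sim$params, sim$schedule,
                               noise_model(cv = 0.07, floor = 0.05),
                               seed = 2, sim = sim)
  expect_true(all(obs$concentrations$value >= 0.05))
  expect_equal(obs$censored_fraction, mean(obs$concentrations$censored))
  expect_gt(obs$censored_fraction, 0)  # butyrate sits near zero post-step
})

test_that("community compositions sum to one at every timepoint", {
  sim <- nh3_sim()
  comm <- community_observation(sim, noise_model(), seed = 3)
  sums <- tapply(comm$abundance, interaction(comm$time, comm$panel), sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-12))
  expect_true(all(comm$abundance >= 0))
})

test_that("the sensitive methanogen share collapses in the observed community", {
  sim <- nh3_sim()
  comm <- community_observation(sim, noise_model(), seed = 4)
  late <- comm[comm$panel == "methanogens" & comm$taxon == "X_ac2" &
                 comm$time >= 75, ]
  expect_true(all(late$abundance < 0.05))
})

test_that("doubling the effective counts roughly halves the sampling variance", {
  sim <- nh3_sim()
  reps <- 300
  share_at <- function(counts, k) {
    comm <- community_observation(sim, noise_model(effective_counts = counts),
                                  seed = 5000 + k, times = 30)
    comm$abundance[comm$panel == "methanogens" & comm$taxon == "X_ac2"]
  }
  v100 <- var(sapply(seq_len(reps), function(k) share_at(100, k)))
  v200 <- var(sapply(seq_len(reps), function(k) share_at(200, k)))
  # Dirichlet component variance scales ~ 1/(counts + 1)
  expect_equal(v100 / v200, 201 / 101, tolerance = 0.35)
})
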