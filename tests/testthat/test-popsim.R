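test_that("deathless unconstrained growth is pure doubling", {
  r <- simulate_population(sim_config(degree_cap = NULL, p_death = 0,
                                      volume_limited = FALSE, generations = 5,
                                      seed = 1))
  expect_equal(r$per_generation$living, 2^(1:5))
  expect_equal(nrow(r$clusters), 1)
  expect_equal(r$clusters$living, 32)
})

test_that("certain death prunes every cell the generation after its birth", {
  # newborns are protected in their birth generation, so p = 1 leaves a
  # single immortal budding lineage trailing one-cell corpses
  r <- simulate_population(sim_config(degree_cap = NULL, p_death = 1,
                                      volume_limited = FALSE, generations = 1,
                                      seed = 1))
  expect_equal(tail(r$per_generation$living, 1), 1) # the newborn survives
  expect_equal(nrow(r$clusters), 2)                 # dead founder split off
  expect_equal(sort(r$clusters$total), c(1, 1))
  expect_equal(sum(r$clusters$living), 1)

  r5 <- simulate_population(sim_config(degree_cap = NULL, p_death = 1,
                                       volume_limited = FALSE, generations = 5,
                                       seed = 1))
  expect_equal(r5$per_generation$living, rep(1, 5))
  expect_equal(r5$per_generation$deaths, rep(1, 5))
})

test_that("the engine matches the reference grower cell for cell", {
  # same rules, independent implementations: deterministic p = 0 runs
  cases <- list(list(cap = NULL, vol = FALSE, t = 8),
                list(cap = 3L, vol = FALSE, t = 10),
                list(cap = 4L, vol = TRUE, t = 16),
                list(cap = NULL, vol = TRUE, t = 13))
  for (cs in cases) {
    r <- simulate_population(sim_config(degree_cap = cs$cap, p_death = 0,
                                        volume_limited = cs$vol,
                                        generations = cs$t, seed = 1))
    cl <- grow(t = cs$t, constraints = growth_constraints(cs$cap, cs$vol))
    expect_equal(tail(r$per_generation$living, 1), n_cells(cl))
    expect_equal(tabulate(r$state$shell + 1L), tabulate(cl$cells$shell + 1L),
                 info = sprintf("cap=%s vol=%s", deparse(cs$cap), cs$vol))
  }
})

test_that("volume constraints block uncapped growth from generation 12 on", {
  r <- simulate_population(sim_config(degree_cap = NULL, p_death = 0,
                                      volume_limited = TRUE, generations = 14,
                                      seed = 1))
  living <- r$per_generation$living
  expect_equal(living[1:11], 2^(1:11)) # no limit before the first overflow
  expect_lt(living[12], 2^12)
  expect_lt(living[14], 2^14)
})

test_that("shell occupancy never exceeds capacity in volume-limited runs", {
  r <- simulate_population(sim_config(degree_cap = 4, p_death = 0.05,
                                      volume_limited = TRUE, generations = 21,
                                      seed = 7))
  shells_by_cluster <- split(r$state$shell, r$state$cluster)
  ok <- vapply(shells_by_cluster, function(sh) {
    occ <- cumsum(tabulate(sh + 1L, nbins = max(sh) + 1L))
    all(occ <= shell_capacity(0:max(sh)))
  }, logical(1))
  expect_true(all(ok))
})

test_that("susceptibility honors newborn protection and the death delay", {
  cells <- data.frame(alive = c(TRUE, TRUE, TRUE, FALSE),
                      birth_gen = c(2L, 2L, 5L, 1L),
                      last_repro_gen = c(5L, 3L, 5L, 1L))
  # a cell that just budded is still in the lottery at delay 0; a cell born
  # this generation is not; dead cells never are
  expect_equal(susceptible(cells, gen = 5, delay = 0),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(susceptible(cells, gen = 5, delay = 1),
               c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(susceptible(cells, gen = 8, delay = 5),
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("delayed death protects cells that just reproduced", {
  # delay 5 with a 5-generation run: nothing has been idle long enough
  r <- simulate_population(sim_config(degree_cap = NULL, p_death = 1,
                                      death_delay = 5, volume_limited = FALSE,
                                      generations = 5, seed = 1))
  expect_equal(r$per_generation$deaths, rep(0, 5))
  expect_equal(tail(r$per_generation$living, 1), 32)
})

test_that("cells are conserved through every generation and split", {
  r <- simulate_population(sim_config(degree_cap = 3, p_death = 0.1,
                                      generations = 15, seed = 42))
  pg <- r$per_generation
  living <- c(1, pg$living) # founder before generation 1
  expect_equal(pg$living, living[-length(living)] + pg$births - pg$deaths)
  total <- pg$living + pg$dead
  expect_true(all(diff(total) >= 0)) # cells never vanish
  # each split partitions its parent cluster
  expect_equal(r$splits$parent_size,
               r$splits$fragment_kept + r$splits$fragment_severed)
  # cluster count grows by exactly one per severance
  expect_equal(tail(pg$clusters, 1), 1 + nrow(r$splits))
  # per-cluster totals recompute from the raw state
  expect_equal(r$clusters$living, state_living_by_cluster(r$state))
})

test_that("identical seeds reproduce the run exactly", {
  cfg <- sim_config(degree_cap = 3, p_death = 0.05, generations = 12, seed = 99)
  r1 <- simulate_population(cfg)
  r2 <- simulate_population(cfg)
  expect_identical(r1$per_generation, r2$per_generation)
  expect_identical(r1$state, r2$state)
  r3 <- simulate_population(sim_config(degree_cap = 3, p_death = 0.05,
                                       generations = 12, seed = 100))
  expect_false(identical(r1$per_generation, r3$per_generation))
})

test_that("threshold counts filter clusters by living size", {
  fake <- list(clusters = data.frame(cluster = 1:3, living = c(30, 10, 3),
                                     total = c(35, 12, 3), diameter = c(9, 5, 2)))
  expect_equal(clusters_above_threshold(fake, 1, "clusters"), 3)
  expect_equal(clusters_above_threshold(fake, 25, "clusters"), 1)
  expect_equal(clusters_above_threshold(fake, 25, "cells"), 30)
  expect_equal(clusters_above_threshold(fake, 100, "clusters"), 0)
  expect_equal(clusters_above_threshold(fake, 1, "cells"), 43)
})

test_that("a single-strategy sweep reduces to plain simulations", {
  sw <- strategy_sweep(caps = list(3L), p_deaths = 0.05, delays = 0,
                       thetas = 1, replicates = 1, seed = 10,
                       generations = 10)
  cfg <- sim_config(degree_cap = 3, p_death = 0.05, generations = 10,
                    seed = (10 + 7919L * 1L + 1L) %% .Machine$integer.max)
  r <- simulate_population(cfg)
  expect_equal(sw$mean_cells, sum(r$clusters$living))
  expect_equal(sw$mean_clusters, sum(r$clusters$living >= 1))
  # rerunning gives the identical table (replicate seeds are derived)
  sw2 <- strategy_sweep(caps = list(3L), p_deaths = 0.05, delays = 0,
                        thetas = 1, replicates = 1, seed = 10,
                        generations = 10)
  expect_identical(sw, sw2)
})

test_that("population clusters export as valid lineage trees", {
  r <- simulate_population(sim_config(degree_cap = 3, p_death = 0.1,
                                      generations = 10, seed = 3))
  ids <- r$clusters$cluster[order(-r$clusters$total)][1:3]
  for (cid in ids) {
    cl <- population_cluster(r, cid)
    validate_cluster(cl, degree_cap = 3)
    expect_equal(n_cells(cl), r$clusters$total[r$clusters$cluster == cid])
  }
})
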