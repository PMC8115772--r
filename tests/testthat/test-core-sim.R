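test_that("initialization splits sizes and labels evenly", {
  cfg <- sim_config(N = 5000, S = 200, A0 = 25, R = 1, timesteps = 1)
  pop <- initialize_population(cfg)
  expect_true(all(pop$subpop_sizes == 25))
  # every subpopulation holds each label exactly once
  for (s in c(1, 57, 200)) {
    expect_setequal(pop$traits[pop$subpop_of == s], 0:24)
  }
  expect_equal(richness(pop), 25)
  expect_equal(fst(pop), 0)
  expect_equal(pop$next_label, 25)

  cfg2 <- sim_config(N = 10, S = 3, A0 = 1, R = 1, timesteps = 1)
  pop2 <- initialize_population(cfg2)
  expect_equal(pop2$subpop_sizes, c(4L, 3L, 3L))
  expect_true(all(pop2$traits == 0))

  cfg3 <- sim_config(N = 5000, S = 150, A0 = 33, R = 1, timesteps = 1)
  pop3 <- initialize_population(cfg3)
  expect_equal(sum(pop3$subpop_sizes == 34), 50)
  expect_equal(sum(pop3$subpop_sizes == 33), 100)
  for (s in c(1, 50, 51, 150)) {
    expect_setequal(pop3$traits[pop3$subpop_of == s], 0:32)
  }
})

test_that("an even initial distribution larger than a subpopulation is rejected", {
  expect_error(sim_config(N = 10, S = 3, A0 = 4, timesteps = 1), "A0")
  expect_error(sim_config(N = 10, S = 3, A0 = 0, timesteps = 1), "A0")
})

test_that("config validation catches out-of-range parameters", {
  expect_error(sim_config(N = 5, S = 10, timesteps = 1), "N >= S")
  expect_error(sim_config(N = 10, S = 2, m = 1.5, timesteps = 1), "m must")
  expect_error(sim_config(N = 10, S = 2, mu = -0.1, timesteps = 1), "mu must")
  expect_error(sim_config(N = 10, S = 2, timesteps = 0), "timesteps")
  expect_error(sim_config(N = 10, S = 2, timesteps = 5, R = 0), "R must")
})

test_that("a fixed subpopulation is absorbing under pure drift", {
  pop <- trait_population(list(rep(3L, 10), c(0L, 1L, 0L, 1L)))
  net <- as_interaction_network(cbind(1, 2), n_nodes = 2)
  set.seed(1)
  for (t in 1:20) {
    pop <- wf_step(pop, net, m = 0, mu = 0)
    expect_true(all(pop$traits[pop$subpop_of == 1] == 3L))
  }
})

test_that("mu = 1 replaces every copy with a fresh label", {
  cfg <- sim_config(N = 60, S = 3, A0 = 10, mu = 1, m = 0.5, timesteps = 1, R = 1)
  net <- build_small_world(3, 2, 0, 1)
  set.seed(2)
  pop <- wf_step(initialize_population(cfg), net, m = 0.5, mu = 1)
  expect_equal(richness(pop), 60)
  expect_equal(pop$next_label, 10L + 60L)
  expect_false(any(pop$traits < 10))
})

test_that("subpopulation sizes are conserved and richness never grows without innovation", {
  cfg <- sim_config(N = 90, S = 4, A0 = 20, m = 0.1, mu = 0, timesteps = 1, R = 1)
  net <- build_small_world(4, 2, 0, 1)
  set.seed(3)
  pop <- initialize_population(cfg)
  sizes0 <- pop$subpop_sizes
  rich <- richness(pop)
  for (t in 1:60) {
    pop <- wf_step(pop, net, m = 0.1, mu = 0)
    sz <- tabulate(pop$subpop_of, nbins = 4)
    expect_identical(sz, sizes0)
    r <- richness(pop)
    expect_lte(r, rich)
    rich <- r
  }
  expect_equal(pop$t, 60L)
})

test_that("replicates are bit-identical under the same seed", {
  cfg <- sim_config(N = 100, S = 5, A0 = 10, m = 0.02, mu = 0.001,
                    timesteps = 40, R = 1, stat_interval = 10)
  net <- build_small_world(5, 2, 0.2, seed = 9)
  a <- run_replicate(cfg, net, replicate_seed = 123)
  b <- run_replicate(cfg, net, replicate_seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- run_replicate(cfg, net, replicate_seed = 124)
  expect_false(identical(a$fst, c$fst))
})

test_that("snapshots honour the cadence contract", {
  cfg <- sim_config(N = 20, S = 2, A0 = 5, m = 0, timesteps = 1, R = 1)
  s <- run_replicate(cfg, NULL, replicate_seed = 1)
  expect_equal(s$timestep, c(0, 1))

  cfg2 <- sim_config(N = 20, S = 2, A0 = 5, m = 0, timesteps = 25, R = 1,
                     stat_interval = 10)
  s2 <- run_replicate(cfg2, NULL, replicate_seed = 1)
  expect_equal(s2$timestep, c(0, 10, 20, 25))
})

test_that("isolated nodes fall back to within-group copying", {
  # node 3 has no neighbours; with m = 1 nodes 1 and 2 swap sources but the
  # isolated subpopulation keeps drifting on its own labels {6, 7}
  net <- as_interaction_network(cbind(1, 2), n_nodes = 3)
  pop <- trait_population(list(c(0L, 1L), c(2L, 3L), c(6L, 7L)))
  set.seed(4)
  for (t in 1:10) {
    pop <- wf_step(pop, net, m = 1, mu = 0)
    expect_true(all(pop$traits[pop$subpop_of == 3] %in% c(6L, 7L)))
  }
})

test_that("heterozygosity decays as (1 - 1/N)^t under single-population drift", {
  # closed-form neutral Wright-Fisher decay, checked by Monte Carlo
  cfg <- sim_config(N = 25, S = 1, A0 = 25, m = 0, mu = 0, timesteps = 50,
                    R = 1, stat_interval = 50)
  reps <- run_replicates(cfg, NULL, 2000, seed_base = 4242)
  h50 <- final_stat(reps, "heterozygosity")
  expected <- 0.96 * (1 - 1 / 25)^50      # ~ 0.1247
  se <- stats::sd(h50) / sqrt(length(h50))
  expect_lt(abs(mean(h50) - expected), 3 * se)
})

test_that("derived seeds are distinct, stable and in range", {
  s <- derive_seed(20260401, 1:5000)
  expect_equal(anyDuplicated(s), 0)
  expect_true(all(s >= 1 & s <= 2147483646))
  expect_identical(derive_seed(7, 3), derive_seed(7, 3))
  expect_false(derive_seed(7, 3) == derive_seed(8, 3))
})

test_that("the step rejects a network whose size disagrees with the population", {
  cfg <- sim_config(N = 20, S = 4, A0 = 5, timesteps = 1, R = 1)
  net <- build_small_world(5, 2, 0, 1)
  pop <- initialize_population(cfg)
  expect_error(wf_step(pop, net, m = 0.1, mu = 0), "nodes")
})
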