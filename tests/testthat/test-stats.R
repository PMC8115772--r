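test_that("frequency tables hold exact counts, weights and global means", {
  pop <- trait_population(list(c(0L, 0L), c(1L, 1L)))
  ft <- trait_frequencies(pop)
  expect_equal(ft$labels, c(0L, 1L))
  expect_equal(ft$freq, matrix(c(1, 0, 0, 1), nrow = 2))
  expect_equal(ft$global_freq, c(0.5, 0.5))
  expect_equal(rowSums(ft$freq), c(1, 1))
  expect_equal(sum(ft$weights), 1)

  single <- trait_population(list(c(0L, 0L, 1L, 2L)))
  fts <- trait_frequencies(single)
  expect_equal(as.numeric(fts$freq), fts$global_freq)

  # sizes (4,3,3), label-0 counts (2,3,0): size-weighted global p0 = 0.5
  pop3 <- trait_population(list(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L), c(1L, 1L, 1L)))
  ft3 <- trait_frequencies(pop3)
  expect_equal(ft3$global_freq[ft3$labels == 0], 0.5)
})

test_that("F_ST hits its boundary and hand-computed values", {
  # two equal subpopulations fixed on different labels: maximal differentiation
  expect_equal(fst(trait_population(list(c(0L, 0L), c(1L, 1L)))), 1)
  # identical subpopulations: no differentiation
  expect_equal(fst(trait_population(list(c(0L, 1L), c(0L, 1L)))), 0)
  # monomorphic population (denominator zero by convention)
  expect_equal(fst(trait_population(list(c(5L, 5L), c(5L, 5L)))), 0)
  # three equal subpopulations, biallelic freqs 0.2/0.4/0.6: F_ST = 1/9
  pop <- trait_population(list(
    c(0L, rep(1L, 4)), c(0L, 0L, rep(1L, 3)), c(0L, 0L, 0L, 1L, 1L)
  ))
  expect_equal(fst(pop), 1 / 9, tolerance = 1e-12)
})

test_that("richness, heterozygosity and unique counts follow their definitions", {
  expect_equal(richness(trait_population(list(rep(0L, 7)))), 1)
  expect_equal(richness(trait_population(list(c(0L, 0L, 1L), c(3L, 3L, 7L)))), 4)

  expect_equal(heterozygosity(trait_population(list(rep(2L, 10)))), 0)
  expect_equal(heterozygosity(trait_population(list(c(0L, 0L, 1L, 1L)))), 0.5)
  # global frequencies (0.5, 0.25, 0.25)
  expect_equal(heterozygosity(trait_population(list(c(0L, 0L, 1L, 2L)))), 0.625)

  # label sets {1,2}, {2,3}, {2}: subpops 1 and 2 hold private labels
  pop <- trait_population(list(c(1L, 2L), c(2L, 3L), c(2L, 2L)))
  expect_equal(unique_trait_subpops(pop), 2)
  expect_equal(unique_trait_subpops(
    trait_population(list(c(0L, 1L), c(0L, 1L)))), 0)
  expect_equal(unique_trait_subpops(
    trait_population(list(c(0L, 0L), c(1L, 1L), c(2L, 2L)))), 3)
})

test_that("all statistics match brute-force recomputation on random instances", {
  for (i in 1:100) {
    pop <- random_population(1000 + i)
    expect_equal(fst(pop), brute_fst(pop), tolerance = 1e-12)
    expect_identical(richness(pop), brute_richness(pop))
    expect_equal(heterozygosity(pop), brute_heterozygosity(pop),
                 tolerance = 1e-12)
    expect_identical(as.integer(unique_trait_subpops(pop)),
                     as.integer(brute_unique_trait_subpops(pop)))
    f <- fst(pop)
    expect_gte(f, 0)
    expect_lte(f, 1)
  }
})

test_that("F_ST is invariant to trait relabeling and subpopulation permutation", {
  for (i in 1:20) {
    pop <- random_population(2000 + i)
    f0 <- fst(pop)
    # relabel traits by a random bijection
    labs <- sort(unique(pop$traits))
    perm <- sample(seq_along(labs) + 100L)
    pop_rl <- pop
    pop_rl$traits <- perm[match(pop$traits, labs)]
    pop_rl$next_label <- max(pop_rl$traits) + 1L
    expect_equal(fst(pop_rl), f0, tolerance = 1e-12)
    # permute subpopulation order
    S <- length(pop$subpop_sizes)
    ord <- sample(S)
    by_sub <- lapply(seq_len(S), function(s) pop$traits[pop$subpop_of == s])
    expect_equal(fst(trait_population(by_sub[ord])), f0, tolerance = 1e-12)
  }
})

test_that("replicate aggregation reproduces the Student-t interval", {
  cfg <- sim_config(N = 12, S = 2, A0 = 3, m = 0, timesteps = 2, R = 1)
  base <- run_replicate(cfg, NULL, replicate_seed = 1)
  # three synthetic replicates with richness 1, 2, 3 at the final snapshot
  series <- lapply(1:3, function(v) {
    s <- base
    s$richness <- rep(v, nrow(s))
    s
  })
  agg <- aggregate_replicates(series)
  fin <- agg[agg$statistic == "richness" & agg$timestep == 2, ]
  expect_equal(fin$mean, 2)
  expect_equal(fin$ci_high, 2 + stats::qt(0.975, 2) * 1 / sqrt(3),
               tolerance = 1e-12)
  # lower band clipped to richness' valid range [1, Inf)
  expect_equal(fin$ci_low, 1)

  pc <- aggregate_replicates(series, method = "percentile")
  finp <- pc[pc$statistic == "richness" & pc$timestep == 2, ]
  expect_equal(finp$ci_low, stats::quantile(1:3, 0.025, names = FALSE))
})

test_that("degenerate and identical-replicate aggregations collapse to the mean", {
  cfg <- sim_config(N = 12, S = 2, A0 = 3, m = 0, timesteps = 3, R = 1)
  one <- run_replicate(cfg, NULL, replicate_seed = 5)
  agg1 <- aggregate_replicates(list(one))
  expect_true(attr(agg1, "degenerate"))
  expect_equal(agg1$ci_low, agg1$mean)
  expect_equal(agg1$ci_high, agg1$mean)

  agg2 <- aggregate_replicates(list(one, one, one))
  expect_false(attr(agg2, "degenerate"))
  expect_equal(agg2$ci_low, agg2$mean)
  expect_equal(agg2$ci_high, agg2$mean)
})

test_that("aggregation refuses mismatched snapshot grids", {
  cfg1 <- sim_config(N = 12, S = 2, A0 = 3, m = 0, timesteps = 4, R = 1,
                     stat_interval = 2)
  cfg2 <- sim_config(N = 12, S = 2, A0 = 3, m = 0, timesteps = 4, R = 1,
                     stat_interval = 1)
  a <- run_replicate(cfg1, NULL, replicate_seed = 1)
  b <- run_replicate(cfg2, NULL, replicate_seed = 1)
  expect_error(aggregate_replicates(list(a, b)), "mismatched")
})
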