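# Independent brute-force recomputations of every statistic, written as plain
# loops over raw labels so they share no code with the package implementation.

brute_richness <- function(pop) length(unique(pop$traits))

brute_heterozygosity <- function(pop) {
  N <- length(pop$traits)
  same <- 0
  for (a in unique(pop$traits)) same <- same + (sum(pop$traits == a) / N)^2
  1 - same
}

brute_fst <- function(pop) {
  N <- length(pop$traits)
  S <- length(pop$subpop_sizes)
  labels <- unique(pop$traits)
  num <- 0
  den <- 0
  for (a in labels) {
    f <- numeric(S)
    for (s in seq_len(S)) {
      mem <- pop$traits[pop$subpop_of == s]
      f[s] <- mean(mem == a)
    }
    p <- sum((pop$subpop_sizes / N) * f)
    sigma2 <- sum((pop$subpop_sizes / N) * (f - p)^2)
    num <- num + sigma2
    den <- den + p * (1 - p)
  }
  if (den == 0) 0 else num / den
}

brute_unique_trait_subpops <- function(pop) {
  S <- length(pop$subpop_sizes)
  sets <- lapply(seq_len(S), function(s) unique(pop$traits[pop$subpop_of == s]))
  holds_private <- vapply(seq_len(S), function(s) {
    others <- unique(unlist(sets[-s]))
    any(!(sets[[s]] %in% others))
  }, logical(1))
  sum(holds_private)
}

# a small random structured population for property tests
random_population <- function(seed) {
  set.seed(seed)
  S <- sample(2:6, 1)
  sizes <- sample(2:8, S, replace = TRUE)
  trait_population(lapply(sizes, function(n) sample(0:5, n, replace = TRUE)))
}

# complete graph as an interaction network (works for any n >= 2, including
# even n where a ring-regular complete graph does not exist)
complete_network <- function(n) {
  as_interaction_network(t(utils::combn(n, 2)), n_nodes = n)
}

run_replicates <- function(cfg, net, n, seed_base) {
  lapply(seq_len(n), function(r) {
    run_replicate(cfg, net, replicate_seed = derive_seed(seed_base, r))
  })
}

final_stat <- function(series, stat) {
  vapply(series, function(s) as.numeric(s[[stat]][nrow(s)]), numeric(1))
}

stat_at <- function(series, stat, t) {
  vapply(series, function(s) as.numeric(s[[stat]][s$timestep == t]), numeric(1))
}
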