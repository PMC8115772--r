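# Forward-time haploid Wright-Fisher transmission kernel with
# network-constrained between-group copying and infinite-alleles innovation.

#' Simulation configuration
#'
#' Collects all model parameters for one simulation condition and validates
#' them. Defaults follow the package's standard study conditions: a
#' between-group interaction rate of 0.25% per individual per timestep, no
#' innovation, an initial trait count of one label per individual slot in a
#' subpopulation (`floor(N / S)`, so every subpopulation starts with an even
#' distribution over all labels), and 10 replicates.
#'
#' @param N total number of individuals (haploid, fixed over time).
#' @param S number of subpopulations; `1 <= S <= N`.
#' @param m between-group interaction probability: the chance, per individual
#'   per timestep, that the individual copies from a network-neighbour
#'   subpopulation rather than its own.
#' @param mu innovation probability per copy event (infinite-alleles: every
#'   innovation is a brand-new label).
#' @param timesteps number of synchronous generations to simulate.
#' @param A0 initial number of distinct trait labels, evenly distributed
#'   within every subpopulation; at most the smallest subpopulation size.
#' @param R number of replicate runs.
#' @param seed master seed; per-replicate streams are derived from it with
#'   [derive_seed()].
#' @param stat_interval timesteps between statistic snapshots (`t = 0` and
#'   `t = timesteps` are always included).
#' @param network optional network specification carried along with the
#'   config: either an `interaction_network` or a named list builder spec
#'   understood by [build_network()].
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(N, S, m = 0.0025, mu = 0, timesteps = 2000,
                       A0 = NULL, R = 10, seed = 1L, stat_interval = 1L,
                       network = NULL) {
  N <- as.integer(N); S <- as.integer(S)
  if (is.na(N) || is.na(S) || N < 1 || S < 1 || N < S) {
    stop("need N >= S >= 1")
  }
  if (is.null(A0)) A0 <- N %/% S
  A0 <- as.integer(A0)
  min_size <- N %/% S
  if (A0 < 1 || A0 > min_size) {
    stop(sprintf("A0 must be in [1, floor(N/S)] = [1, %d] (got %d): an even initial distribution needs A0 distinct labels in the smallest subpopulation",
                 min_size, A0))
  }
  if (m < 0 || m > 1) stop("m must be a probability in [0, 1]")
  if (mu < 0 || mu > 1) stop("mu must be a probability in [0, 1]")
  timesteps <- as.integer(timesteps)
  if (timesteps < 1) stop("timesteps must be at least 1")
  R <- as.integer(R)
  if (R < 1) stop("R must be at least 1")
  stat_interval <- as.integer(stat_interval)
  if (stat_interval < 1) stop("stat_interval must be at least 1")
  cfg <- list(N = N, S = S, m = m, mu = mu, timesteps = timesteps, A0 = A0,
              R = R, seed = as.integer(seed), stat_interval = stat_interval,
              network = network)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> N=%d S=%d m=%g mu=%g timesteps=%d A0=%d R=%d seed=%d stat_interval=%d\n",
    x$N, x$S, x$m, x$mu, x$timesteps, x$A0, x$R, x$seed, x$stat_interval
  ))
  invisible(x)
}

#' Derive a stream seed from a master seed
#'
#' Deterministic integer derivation used everywhere a replicate, sweep cell or
#' network build needs its own reproducible stream: a multiplicative
#' linear-congruential jump (multiplier 48271, modulus 2^31 - 1) applied to
#' the master seed plus the stream index. Distinct indices give distinct
#' seeds; all results lie in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param index positive integer stream index (vectorised).
#' @return Integer seed(s), the same length as `index`.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647              # 2^31 - 1, prime
  x <- (abs(as.numeric(master)) %% m + as.numeric(index)) %% m
  as.integer(((x + 1) * 48271) %% m + 1)
}

#' Initialize a structured trait population
#'
#' Splits `N` individuals into `S` subpopulations of size `floor(N / S)`,
#' distributing the remainder one each to the lowest-index subpopulations.
#' Within every subpopulation, labels `0 .. A0 - 1` are assigned cyclically
#' (individual `j` gets `j %% A0`), so all subpopulations start identical and
#' every label sits as close to frequency `1 / A0` as integer counts allow.
#' The resulting state has global richness `A0` and F_ST exactly 0.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `trait_population`: a list with integer vectors
#'   `traits` (label per individual, individuals ordered by subpopulation) and
#'   `subpop_of`, plus `subpop_sizes`, `offsets` (cumulative size index into
#'   the individual vector), `t` and `next_label`.
#' @export
initialize_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  N <- cfg$N; S <- cfg$S; A0 <- cfg$A0
  sizes <- rep(N %/% S, S)
  rem <- N %% S
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes <- as.integer(sizes)
  traits <- unlist(lapply(sizes, function(n) (seq_len(n) - 1L) %% A0),
                   use.names = FALSE)
  pop <- list(
    traits = as.integer(traits),
    subpop_of = rep(seq_len(S), sizes),
    subpop_sizes = sizes,
    offsets = c(0L, cumsum(sizes)),
    t = 0L,
    next_label = A0
  )
  class(pop) <- "trait_population"
  pop
}

#' Construct a trait population from per-subpopulation label vectors
#'
#' Builds a `trait_population` directly from observed (or hand-written) trait
#' labels, one integer vector per subpopulation. Useful for computing the
#' package's statistics on data that did not come out of the simulator.
#'
#' @param traits_by_subpop list of non-negative integer vectors, one per
#'   subpopulation, each of length at least 1.
#' @param t timestep tag, default 0.
#' @return A `trait_population`.
#' @examples
#' pop <- trait_population(list(c(0, 0), c(1, 1)))
#' fst(pop)  # 1: completely differentiated
#' @export
trait_population <- function(traits_by_subpop, t = 0L) {
  stopifnot(is.list(traits_by_subpop), length(traits_by_subpop) >= 1)
  sizes <- lengths(traits_by_subpop)
  if (any(sizes < 1)) stop("every subpopulation needs at least one individual")
  traits <- as.integer(unlist(traits_by_subpop, use.names = FALSE))
  if (any(traits < 0)) stop("trait labels must be non-negative integers")
  pop <- list(
    traits = traits,
    subpop_of = rep(seq_along(sizes), sizes),
    subpop_sizes = as.integer(sizes),
    offsets = c(0L, cumsum(as.integer(sizes))),
    t = as.integer(t),
    next_label = max(traits) + 1L
  )
  class(pop) <- "trait_population"
  pop
}

#' @export
print.trait_population <- function(x, ...) {
  cat(sprintf(
    "<trait_population> N=%d, S=%d, t=%d, richness=%d, next_label=%d\n",
    length(x$traits), length(x$subpop_sizes), x$t,
    length(unique(x$traits)), x$next_label
  ))
  invisible(x)
}

#' One synchronous Wright-Fisher transmission step
#'
#' Advances the population one timestep. Independently for every individual:
#' (1) a source subpopulation is chosen -- its own with probability `1 - m`,
#' otherwise a uniformly chosen network neighbour of its subpopulation (a
#' subpopulation with no neighbours always copies from itself); (2) the
#' individual copies the trait of a uniformly chosen member (sampling with
#' replacement) of the source subpopulation *as it was at time t*; (3) with
#' probability `mu` the copied trait is replaced by a brand-new label
#' (infinite alleles). Subpopulation sizes never change. The update is
#' synchronous: all copies read the time-`t` state.
#'
#' The random stream is consumed in fixed-size blocks (one uniform draw per
#' individual per decision), so the stream position after a step depends only
#' on `(N, m > 0, mu > 0)` and never on branch outcomes.
#'
#' @param pop a `trait_population` from [initialize_population()].
#' @param net an `interaction_network` with `S` nodes (node `s` is
#'   subpopulation `s`).
#' @param m between-group copy probability per individual.
#' @param mu innovation probability per copy event.
#' @return The updated `trait_population` at time `t + 1`.
#' @export
wf_step <- function(pop, net, m, mu) {
  N <- length(pop$traits)
  S <- length(pop$subpop_sizes)
  if (!is.null(net)) {
    stopifnot(inherits(net, "interaction_network"))
    if (net$n_nodes != S) {
      stop(sprintf("network has %d nodes but the population has %d subpopulations",
                   net$n_nodes, S))
    }
  }
  src <- pop$subpop_of
  if (m > 0 && !is.null(net) && any(net$deg > 0)) {
    u_mig <- stats::runif(N)
    u_nb <- stats::runif(N)
    deg_own <- net$deg[src]
    migrate <- u_mig < m & deg_own > 0L
    if (any(migrate)) {
      pick <- net$nb_off[src] + pmin(floor(u_nb * deg_own) + 1L, deg_own)
      src[migrate] <- net$nb_flat[pick[migrate]]
    }
  }
  sz <- pop$subpop_sizes[src]
  u_ind <- stats::runif(N)
  idx <- pop$offsets[src] + pmin(floor(u_ind * sz) + 1L, sz)
  new_traits <- pop$traits[idx]
  if (mu > 0) {
    u_mut <- stats::runif(N)
    innov <- u_mut < mu
    n_new <- sum(innov)
    if (n_new > 0) {
      new_traits[innov] <- pop$next_label + seq_len(n_new) - 1L
      pop$next_label <- pop$next_label + as.integer(n_new)
    }
  }
  pop$traits <- as.integer(new_traits)
  pop$t <- pop$t + 1L
  pop
}

#' Run one replicate and record statistic snapshots
#'
#' Initializes the population from `cfg`, applies [wf_step()] for
#' `cfg$timesteps` generations under its own seeded stream, and snapshots the
#' four tracked statistics (F_ST, richness, unique-trait subpopulation count,
#' heterozygosity) every `cfg$stat_interval` timesteps, always including
#' `t = 0` and the final timestep. Identical `(cfg, net, replicate_seed)`
#' reproduce an identical series.
#'
#' @param cfg a [sim_config()].
#' @param net an `interaction_network` with `cfg$S` nodes; may be `NULL` when
#'   `cfg$m == 0` or `cfg$S == 1`.
#' @param replicate_seed seed for this replicate's random stream (defaults to
#'   `derive_seed(cfg$seed, 1)`).
#' @return A `stat_series`: a data frame with columns `timestep`, `fst`,
#'   `richness`, `unique_trait_subpops`, `heterozygosity`, carrying the
#'   replicate seed, the config echo and network metadata as attributes.
#' @export
run_replicate <- function(cfg, net = NULL, replicate_seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(net) && !is.null(cfg$network)) net <- build_network(cfg$network, S = cfg$S)
  if (is.null(net) && cfg$m > 0 && cfg$S > 1) {
    stop("a network is required when m > 0 and S > 1")
  }
  if (is.null(replicate_seed)) replicate_seed <- derive_seed(cfg$seed, 1L)
  with_seed(replicate_seed, {
    pop <- initialize_population(cfg)
    snap_at <- unique(sort(c(0L, seq(cfg$stat_interval, cfg$timesteps,
                                     by = cfg$stat_interval), cfg$timesteps)))
    rows <- vector("list", length(snap_at))
    ri <- 1L
    rows[[ri]] <- snapshot_stats(pop)
    for (t in seq_len(cfg$timesteps)) {
      pop <- wf_step(pop, net, cfg$m, cfg$mu)
      if (t %% cfg$stat_interval == 0L || t == cfg$timesteps) {
        ri <- ri + 1L
        rows[[ri]] <- snapshot_stats(pop)
      }
    }
    out <- do.call(rbind, rows[seq_len(ri)])
    attr(out, "replicate_seed") <- as.integer(replicate_seed)
    attr(out, "config") <- cfg
    attr(out, "network_meta") <- if (!is.null(net)) {
      c(list(builder = net$builder), net$params)
    }
    class(out) <- c("stat_series", "data.frame")
    out
  })
}

snapshot_stats <- function(pop) {
  ft <- trait_frequencies(pop)
  data.frame(
    timestep = pop$t,
    fst = fst(ft),
    richness = length(ft$labels),
    unique_trait_subpops = unique_trait_subpops(pop),
    heterozygosity = 1 - sum(ft$global_freq^2)
  )
}

#' Build a network from a builder specification
#'
#' A builder spec is a named list with a `type` field: `small_world` (fields
#' `k`, `p_rewire`, `seed`), `spatial_knn` (fields `k` plus either `points`, a
#' [point_set()], or island-generator arguments `n`, `seed`, ...), or `custom`
#' (field `edges`). Passing an `interaction_network` returns it unchanged.
#'
#' @param spec builder spec list or an `interaction_network`.
#' @param S expected node count (used for validation and as the default
#'   `n_nodes`).
#' @return An `interaction_network`.
#' @export
build_network <- function(spec, S = NULL) {
  if (inherits(spec, "interaction_network")) {
    if (!is.null(S) && spec$n_nodes != S) {
      stop(sprintf("network has %d nodes, expected %d", spec$n_nodes, S))
    }
    return(spec)
  }
  if (!is.list(spec) || is.null(spec$type)) {
    stop("network spec must be an interaction_network or a list with a 'type' field")
  }
  type <- spec$type
  if (type == "small_world") {
    n <- spec$n_nodes %||% S
    build_small_world(n, k = spec$k,
                      p_rewire = spec$p_rewire %||% 0,
                      seed = spec$seed %||% 1L)
  } else if (type == "spatial_knn") {
    pts <- spec$points
    if (is.null(pts)) {
      res <- generate_connected_island(
        n = spec$n_points %||% S, k = spec$k,
        seed = spec$seed %||% 1L,
        mean_radius = spec$mean_radius %||% 8000,
        irregularity = spec$irregularity %||% 0.25,
        jitter = spec$jitter %||% 400
      )
      return(res$network)
    }
    build_spatial_knn(pts, k = spec$k)
  } else if (type == "custom") {
    as_interaction_network(spec$edges, n_nodes = spec$n_nodes %||% S)
  } else {
    stop(sprintf("unknown network type '%s'", type))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
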