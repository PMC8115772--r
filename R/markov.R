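# Exact Markov-chain oracle for the transmission kernel on tiny instances.

# All compositions of n into L non-negative parts, as rows of a matrix.
compositions <- function(n, L) {
  if (L == 1) return(matrix(n, ncol = 1))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, L - 1)
    out[[first + 1]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Exact state distribution of the transmission chain on a tiny instance
#'
#' Enumerates every trait-count state of a small structured population (a
#' composition of each subpopulation's size over the initial labels, with
#' innovation disabled), builds the one-step transition matrix implied by the
#' synchronous copy kernel analytically, and returns the exact distribution
#' after `t` steps from the [initialize_population()] state. For each
#' subpopulation `s` the per-individual probability of copying label `a` is
#' the `m`-weighted source mixture
#' `q_sa = (1 - m) c_sa / n_s + sum_{v in nb(s)} (m / deg_s) c_va / n_v`
#' (a neighbourless node always copies from itself), and the next counts of
#' subpopulation `s` are multinomial `(n_s, q_s)`, independent across
#' subpopulations given the current state.
#'
#' This brute-force chain is an independent oracle for [wf_step()]: the
#' simulator's empirical state distribution must converge to it.
#'
#' @param cfg a [sim_config()] with `mu = 0` (innovation makes the state
#'   space infinite) and a state space of at most `max_states` states.
#' @param net an `interaction_network` with `cfg$S` nodes, or `NULL` when
#'   `m = 0`.
#' @param t number of steps.
#' @param max_states refusal bound on the enumerated state count.
#' @return A list with `states` (list of `S x L` count matrices), `keys`
#'   (canonical string key per state, as produced by [state_key()]), `prob`
#'   (the exact distribution after `t` steps) and `t`.
#' @export
exact_markov_distribution <- function(cfg, net = NULL, t, max_states = 10000) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mu != 0) stop("the exact oracle requires mu = 0 (finite label set)")
  t <- as.integer(t)
  if (t < 0) stop("t must be non-negative")
  pop0 <- initialize_population(cfg)
  sizes <- pop0$subpop_sizes
  S <- cfg$S
  L <- cfg$A0
  per_sub <- lapply(sizes, compositions, L = L)
  n_per <- vapply(per_sub, nrow, integer(1))
  n_states <- prod(n_per)
  if (n_states > max_states) {
    stop(sprintf("state space has %s states, above the limit of %s",
                 format(n_states, big.mark = ","), format(max_states, big.mark = ",")))
  }
  # enumerate the product space: state i is a list of per-subpop count rows
  grid <- as.matrix(expand.grid(lapply(n_per, seq_len)))
  states <- lapply(seq_len(n_states), function(i) {
    do.call(rbind, lapply(seq_len(S), function(s) per_sub[[s]][grid[i, s], ]))
  })
  keys <- vapply(states, function(st) paste(t(st), collapse = ","), character(1))

  deg <- if (is.null(net)) rep(0L, S) else net$deg
  nbrs <- lapply(seq_len(S), function(s) {
    if (is.null(net) || net$deg[s] == 0L) integer(0)
    else net$nb_flat[(net$nb_off[s] + 1L):net$nb_off[s + 1L]]
  })

  P <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    cs <- states[[i]]
    # per-subpop copy probabilities q[s, ] under the m-weighted source mixture
    q <- matrix(0, S, L)
    for (s in seq_len(S)) {
      own <- cs[s, ] / sizes[s]
      if (cfg$m > 0 && deg[s] > 0) {
        mix <- rep(0, L)
        for (v in nbrs[[s]]) mix <- mix + cs[v, ] / sizes[v]
        q[s, ] <- (1 - cfg$m) * own + (cfg$m / deg[s]) * mix
      } else {
        q[s, ] <- own
      }
    }
    for (j in seq_len(n_states)) {
      pj <- 1
      for (s in seq_len(S)) {
        pj <- pj * stats::dmultinom(states[[j]][s, ], prob = q[s, ])
        if (pj == 0) break
      }
      P[i, j] <- pj
    }
  }

  init_counts <- trait_frequencies(pop0)$counts          # S x L
  init_key <- paste(t(init_counts), collapse = ",")
  v <- as.numeric(keys == init_key)
  stopifnot(sum(v) == 1)
  for (step in seq_len(t)) v <- as.numeric(v %*% P)
  list(states = states, keys = keys, prob = v, t = t)
}

#' Canonical state key of a population over a fixed label set
#'
#' Serialises the per-subpopulation counts of the labels `0 .. L - 1` into the
#' same string key used by [exact_markov_distribution()], so empirical
#' simulator outcomes can be tallied against the exact distribution.
#'
#' @param pop a `trait_population` whose labels are all below `L`.
#' @param L number of labels in the oracle's label set.
#' @return A string key.
#' @export
state_key <- function(pop, L) {
  S <- length(pop$subpop_sizes)
  counts <- matrix(
    tabulate(pop$subpop_of + S * pop$traits, nbins = S * L),
    nrow = S, ncol = L
  )
  paste(t(counts), collapse = ",")
}
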