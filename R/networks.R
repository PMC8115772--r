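# Interaction networks over subpopulations: small-world and spatial kNN
# builders, synthetic island point patterns, and summary metrics.

#' Construct an interaction network object
#'
#' Wraps an [igraph::igraph] graph together with provenance metadata and a
#' flattened adjacency representation used by the simulation kernel. Users
#' normally obtain networks from [build_small_world()], [build_spatial_knn()]
#' or [as_interaction_network()] rather than calling this directly.
#'
#' @param graph an undirected, simple `igraph` graph with vertices `1..n`.
#' @param builder character tag recording how the network was built
#'   (`"small_world"`, `"spatial_knn"` or `"custom"`).
#' @param params named list of builder parameters (requested and realized
#'   degree, rewiring probability, seed, ...).
#' @param coords optional two-column matrix or data frame of planar node
#'   coordinates in metres.
#'
#' @return An object of class `interaction_network`: a list with elements
#'   `graph`, `n_nodes`, `builder`, `params`, `coords`, plus the flattened
#'   neighbour structure (`deg`, `nb_flat`, `nb_off`) consumed by [wf_step()].
#' @export
interaction_network <- function(graph, builder = "custom", params = list(),
                                coords = NULL) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::is_directed(graph)) {
    graph <- igraph::as_undirected(graph, mode = "collapse")
  }
  graph <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph, mode = "all")
  adj <- lapply(adj, function(v) sort(as.integer(v)))
  deg <- lengths(adj)
  net <- list(
    graph = graph,
    n_nodes = n,
    builder = builder,
    params = params,
    coords = coords,
    deg = as.integer(deg),
    nb_flat = as.integer(unlist(adj, use.names = FALSE)),
    nb_off = c(0L, cumsum(as.integer(deg)))
  )
  class(net) <- "interaction_network"
  net
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network> %d nodes, %d edges, builder = %s\n",
    x$n_nodes, igraph::ecount(x$graph), x$builder
  ))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params), unlist(lapply(x$params, format)),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Coerce an igraph graph or an edge matrix to an interaction network
#'
#' @param x an `igraph` graph, or a two-column matrix/data frame of 1-based
#'   node index pairs.
#' @param n_nodes node count when `x` is an edge matrix (isolated trailing
#'   nodes cannot be inferred from edges alone).
#' @inheritParams interaction_network
#' @return An `interaction_network`.
#' @export
as_interaction_network <- function(x, n_nodes = NULL, builder = "custom",
                                   params = list(), coords = NULL) {
  if (igraph::is_igraph(x)) {
    return(interaction_network(x, builder = builder, params = params,
                               coords = coords))
  }
  em <- as.matrix(x)
  storage.mode(em) <- "integer"
  if (ncol(em) != 2) stop("edge input must have two columns")
  if (is.null(n_nodes)) n_nodes <- max(em)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  interaction_network(g, builder = builder, params = params, coords = coords)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build a Watts-Strogatz small-world interaction network
#'
#' Starts from a ring lattice in which every node is joined to its `k / 2`
#' nearest neighbours on each side, then rewires each lattice edge
#' independently with probability `p_rewire` to a uniformly chosen target,
#' avoiding self-loops and duplicate edges. With `p_rewire = 0` the result is
#' the pure ring lattice; with `k = n_nodes - 1` it is the complete graph.
#'
#' A ring-regular graph must have even degree, so an odd `k` is reduced to
#' `k - 1` with a warning; both the requested and the realized value are
#' recorded in the network's `params`.
#'
#' @param n_nodes number of subpopulations (vertices); at least 3.
#' @param k requested connectivity: neighbours per node before rewiring
#'   (`2 <= k <= n_nodes - 1`).
#' @param p_rewire per-edge rewiring probability in `[0, 1]`.
#' @param seed integer seed controlling the rewiring draws.
#' @return An `interaction_network` with builder `"small_world"`.
#' @examples
#' ring <- build_small_world(25, k = 2, p_rewire = 0, seed = 1)
#' network_metrics(ring)$mean_degree  # 2
#' @export
build_small_world <- function(n_nodes, k, p_rewire = 0, seed = 1L) {
  if (n_nodes < 3) stop("n_nodes must be at least 3")
  if (k < 2 || k > n_nodes - 1) {
    stop(sprintf("k must satisfy 2 <= k <= n_nodes - 1 (got k = %s, n_nodes = %s)",
                 k, n_nodes))
  }
  if (p_rewire < 0 || p_rewire > 1) stop("p_rewire must be in [0, 1]")
  k_req <- as.integer(k)
  k_real <- k_req
  if (k_real %% 2L == 1L) {
    k_real <- k_real - 1L
    warning(sprintf(
      "odd k = %d reduced to %d: a regular ring lattice has even degree", k_req, k_real
    ))
  }
  g <- with_seed(seed, igraph::sample_smallworld(
    dim = 1, size = n_nodes, nei = k_real %/% 2L, p = p_rewire,
    loops = FALSE, multiple = FALSE
  ))
  interaction_network(
    g,
    builder = "small_world",
    params = list(k_requested = k_req, k_realized = k_real,
                  p_rewire = p_rewire, seed = as.integer(seed))
  )
}

#' Create a set of labelled planar points
#'
#' @param ids unique node labels.
#' @param x,y finite planar coordinates in metres.
#' @return An object of class `point_set` (a data frame with columns
#'   `id`, `x`, `y`).
#' @export
point_set <- function(ids, x, y) {
  if (length(ids) != length(x) || length(x) != length(y)) {
    stop("ids, x and y must have equal length")
  }
  if (length(x) < 2) stop("a point set needs at least 2 points")
  if (anyDuplicated(ids)) stop("point ids must be unique")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("all coordinates must be finite")
  }
  ps <- data.frame(id = ids, x = as.numeric(x), y = as.numeric(y))
  class(ps) <- c("point_set", "data.frame")
  ps
}

#' Build a spatial k-nearest-neighbour interaction network
#'
#' Each node is linked to its `k` nearest other points by planar Euclidean
#' distance (ties broken by lower node index), and the directed kNN relation
#' is symmetrized by union into an undirected graph: a community interacts
#' with at least its `k` nearest neighbours, and also with any community that
#' counts it among its own `k` nearest. The realized mean degree therefore
#' lies in `[k, 2k]` and is recorded in the network's `params`.
#'
#' @param points a [point_set()] (or data frame with columns `id`, `x`, `y`).
#' @param k neighbours per node; `1 <= k < nrow(points)`.
#' @return An `interaction_network` with builder `"spatial_knn"` and node
#'   coordinates attached.
#' @export
build_spatial_knn <- function(points, k) {
  if (!all(c("x", "y") %in% names(points))) {
    stop("points must have columns x and y")
  }
  n <- nrow(points)
  if (k < 1) stop("k must be at least 1")
  if (k >= n) stop(sprintf("k must be smaller than the number of points (%d)", n))
  xy <- cbind(points$x, points$y)
  if (anyDuplicated(xy)) {
    message("duplicate coordinates present; ties broken by node index")
  }
  d <- as.matrix(stats::dist(xy))
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))   # distance, then lower index
    ord <- ord[ord != i][seq_len(k)]
    edges[[i]] <- cbind(i, ord)
  }
  em <- do.call(rbind, edges)
  # union symmetrization: unordered pairs, deduplicated
  em <- cbind(pmin(em[, 1], em[, 2]), pmax(em[, 1], em[, 2]))
  em <- unique(em)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  net <- interaction_network(
    g, builder = "spatial_knn",
    params = list(k = as.integer(k)),
    coords = xy
  )
  net$params$mean_degree_realized <- mean(net$deg)
  net
}

#' Generate a synthetic island point pattern
#'
#' Places `n` points along a closed, radially perturbed circular coastline:
#' evenly spaced angles with angular jitter, a low-frequency radial
#' perturbation (a short random Fourier series) scaled by `irregularity`, and
#' isotropic Gaussian positional jitter. The pattern emulates dispersed
#' coastal community locations on a small island and is fully determined by
#' `seed`. These points are synthetic stand-ins; measured site coordinates
#' can be supplied instead via [read_points_csv()].
#'
#' @param n number of points; at least 3.
#' @param seed integer seed.
#' @param mean_radius mean coastline radius in metres.
#' @param irregularity fraction in `[0, 1)` scaling the low-frequency radial
#'   perturbation (0 gives a perfect circle).
#' @param jitter standard deviation in metres of isotropic positional noise.
#' @return A [point_set()] of `n` points.
#' @examples
#' pts <- generate_island_points(150, seed = 42)
#' net <- build_spatial_knn(pts, k = 5)
#' @export
generate_island_points <- function(n, seed = 1L, mean_radius = 8000,
                                   irregularity = 0.25, jitter = 400) {
  if (n < 3) stop("n must be at least 3")
  if (mean_radius <= 0) stop("mean_radius must be positive")
  if (irregularity < 0 || irregularity >= 1) {
    stop("irregularity must be in [0, 1)")
  }
  with_seed(seed, {
    theta <- sort((seq_len(n) - 1) / n * 2 * pi +
                    stats::runif(n, -pi / n, pi / n))
    # low-frequency coastline shape: harmonics 1..4, amplitudes normalised
    # so the perturbation magnitude never exceeds 1 before scaling
    amp <- stats::runif(4, 0, 1)
    phase <- stats::runif(4, 0, 2 * pi)
    pert <- rep(0, n)
    for (h in 1:4) pert <- pert + amp[h] * cos(h * theta + phase[h])
    if (max(abs(pert)) > 0) pert <- pert / max(abs(pert))
    r <- mean_radius * (1 + irregularity * pert)
    x <- r * cos(theta) + stats::rnorm(n, 0, jitter)
    y <- r * sin(theta) + stats::rnorm(n, 0, jitter)
    point_set(seq_len(n), x, y)
  })
}

#' Summary metrics of an interaction network
#'
#' Reports the realized degree structure, the number of connected components
#' and the characteristic path length: the mean shortest-path length over all
#' connected ordered node pairs. Pairs in different components are excluded
#' and counted separately, so a disconnected network still gets a finite path
#' length over the pairs that can reach each other; a network with no edges
#' has an undefined (`NA`) path length.
#'
#' @param net an `interaction_network`.
#' @return A list with `mean_degree`, `realized_k_per_node`,
#'   `characteristic_path_length`, `n_components`, `n_unreachable_pairs`.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- net$graph
  n <- net$n_nodes
  deg <- as.integer(igraph::degree(g))
  comp <- igraph::components(g)
  n_edges <- igraph::ecount(g)
  if (n_edges == 0) {
    cpl <- NA_real_
    unreachable <- n * (n - 1)
  } else {
    cpl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
    sizes <- comp$csize
    unreachable <- n * (n - 1) - sum(sizes * (sizes - 1))
  }
  list(
    mean_degree = mean(deg),
    realized_k_per_node = deg,
    characteristic_path_length = cpl,
    n_components = comp$no,
    n_unreachable_pairs = as.integer(unreachable)
  )
}

#' Generate island points whose kNN graph is connected
#'
#' Repeatedly draws synthetic island point patterns (advancing the seed) until
#' the spatial kNN network built from them is connected; each retry is
#' reported. Used by the island presets so the default spatial network does
#' not silently split into isolated clusters at small `k`.
#'
#' @inheritParams generate_island_points
#' @param k neighbour count used for the connectivity check.
#' @param max_tries maximum seeds to try before giving up.
#' @return A list with `points` (a `point_set`), `network`
#'   (the connected kNN `interaction_network`) and `seed_used`.
#' @export
generate_connected_island <- function(n, k, seed = 1L, mean_radius = 8000,
                                      irregularity = 0.25, jitter = 400,
                                      max_tries = 20L) {
  s <- as.integer(seed)
  for (i in seq_len(max_tries)) {
    pts <- generate_island_points(n, seed = s, mean_radius = mean_radius,
                                  irregularity = irregularity, jitter = jitter)
    net <- build_spatial_knn(pts, k = k)
    if (network_metrics(net)$n_components == 1L) {
      return(list(points = pts, network = net, seed_used = s))
    }
    message(sprintf("island point pattern with seed %d gives a disconnected k=%d graph; retrying with seed %d",
                    s, k, s + 1L))
    s <- s + 1L
  }
  stop(sprintf("no connected k=%d island network found in %d attempts", k, max_tries))
}
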