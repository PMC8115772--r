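# Configuration files, point/edge CSV readers and writers, run manifests.

config_keys <- c("N", "S", "m", "mu", "timesteps", "A0", "R", "seed",
                 "stat_interval", "network", "axes")
network_keys <- c("type", "k", "p_rewire", "seed", "points_csv", "n_points",
                  "mean_radius", "irregularity", "jitter", "edges")

#' Load a simulation configuration from a YAML file
#'
#' Reads a human-editable YAML config, validates it strictly (unknown keys are
#' errors, never silently ignored) and resolves all defaults, returning a
#' [sim_config()] plus any sweep axis specification. A network block is kept
#' as a builder spec; a `points_csv` path inside it is read immediately via
#' [read_points_csv()], relative to the config file's directory.
#'
#' @param path path to a YAML file with keys among `N`, `S`, `m`, `mu`,
#'   `timesteps`, `A0`, `R`, `seed`, `stat_interval`, `network`, `axes`.
#' @return A `sim_config`; any `axes` block is attached as attribute `"axes"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  # keep short keys like N and S as strings (YAML 1.1 would read them as booleans)
  keep <- function(x) x
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = keep, "bool#no" = keep))
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s (allowed: %s)",
                 paste(unknown, collapse = ", "),
                 paste(config_keys, collapse = ", ")))
  }
  for (key in c("N", "S", "timesteps")) {
    if (is.null(raw[[key]])) stop(sprintf("config key '%s' is required", key))
  }
  net <- raw$network
  if (!is.null(net)) {
    bad <- setdiff(names(net), network_keys)
    if (length(bad)) {
      stop(sprintf("unknown network key(s): %s", paste(bad, collapse = ", ")))
    }
    if (is.null(net$type)) stop("network block needs a 'type' key")
    if (!is.null(net$points_csv)) {
      net$points <- read_points_csv(file.path(dirname(path), net$points_csv))
      net$points_csv <- NULL
    }
  }
  cfg <- sim_config(
    N = raw$N, S = raw$S,
    m = raw$m %||% 0.0025,
    mu = raw$mu %||% 0,
    timesteps = raw$timesteps,
    A0 = raw$A0,
    R = raw$R %||% 10L,
    seed = raw$seed %||% 1L,
    stat_interval = raw$stat_interval %||% 1L,
    network = net
  )
  attr(cfg, "axes") <- raw$axes
  cfg
}

#' Write a resolved configuration back to YAML
#'
#' Dumps every resolved field of a [sim_config()] (and any axes attribute) so
#' that `load_config(write_config(cfg, path))` round-trips identically.
#'
#' @param cfg a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- cfg[c("N", "S", "m", "mu", "timesteps", "A0", "R", "seed",
               "stat_interval")]
  if (!is.null(cfg$network) && !inherits(cfg$network, "interaction_network")) {
    net <- cfg$network
    net$points <- NULL  # inline point sets are not serialised back
    out$network <- net
  }
  ax <- attr(cfg, "axes")
  if (!is.null(ax)) out$axes <- ax
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read planar point coordinates from CSV
#'
#' Expects exactly the header `id,x,y` with planar coordinates in metres.
#' Malformed (non-numeric or missing) coordinate rows are reported with their
#' line numbers; duplicate ids are errors.
#'
#' @param path CSV path.
#' @return A [point_set()].
#' @export
read_points_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("points file '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("id", "x", "y")) {
    if (!col %in% names(df)) {
      stop(sprintf("points CSV '%s' is missing required column '%s'", path, col))
    }
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop(sprintf("non-numeric or non-finite coordinates at line(s): %s",
                 paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  }
  if (anyDuplicated(df$id)) stop("duplicate point ids in points CSV")
  point_set(df$id, x, y)
}

#' Write a point set to CSV
#'
#' @param points a [point_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points[, c("id", "x", "y")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a network as edge-list CSV, GraphML and a metadata sidecar
#'
#' Writes `<prefix>_edges.csv` (columns `source,target`, 1-based node
#' indices), `<prefix>.graphml`, and `<prefix>_meta.json` recording builder,
#' parameters, realized degrees and component count. Node coordinates, when
#' present, go to `<prefix>_points.csv`.
#'
#' @param net an `interaction_network`.
#' @param prefix output path prefix.
#' @return The metadata list, invisibly.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "interaction_network"))
  em <- igraph::as_edgelist(net$graph, names = FALSE)
  df <- data.frame(source = as.integer(em[, 1]), target = as.integer(em[, 2]))
  utils::write.csv(df, paste0(prefix, "_edges.csv"), row.names = FALSE,
                   quote = FALSE)
  igraph::write_graph(net$graph, paste0(prefix, ".graphml"), format = "graphml")
  mx <- network_metrics(net)
  meta <- list(builder = net$builder, params = net$params,
               n_nodes = net$n_nodes,
               n_edges = igraph::ecount(net$graph),
               mean_degree = mx$mean_degree,
               degrees = mx$realized_k_per_node,
               n_components = mx$n_components)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(net$coords)) {
    write_points_csv(point_set(seq_len(net$n_nodes), net$coords[, 1],
                               net$coords[, 2]),
                     paste0(prefix, "_points.csv"))
  }
  invisible(meta)
}

#' Read an edge-list CSV back into an interaction network
#'
#' @param path CSV with columns `source,target`.
#' @param n_nodes optional node count (for trailing isolated nodes).
#' @return An `interaction_network` with builder `"custom"`.
#' @export
read_edges_csv <- function(path, n_nodes = NULL) {
  df <- utils::read.csv(path)
  for (col in c("source", "target")) {
    if (!col %in% names(df)) {
      stop(sprintf("edge CSV '%s' is missing required column '%s'", path, col))
    }
  }
  as_interaction_network(cbind(df$source, df$target), n_nodes = n_nodes)
}

#' Write replicate series in long format
#'
#' One row per replicate, timestep and statistic:
#' `replicate,timestep,statistic,value`, full numeric precision.
#'
#' @param series a `stat_series` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "stat_series")) series <- list(series)
  stats_names <- c("fst", "richness", "unique_trait_subpops", "heterozygosity")
  long <- do.call(rbind, lapply(seq_along(series), function(r) {
    s <- series[[r]]
    do.call(rbind, lapply(stats_names, function(st) {
      data.frame(replicate = r, timestep = s$timestep, statistic = st,
                 value = as.numeric(s[[st]]))
    }))
  }))
  utils::write.csv(format(long, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an aggregated series to CSV
#'
#' Columns `timestep,statistic,mean,ci_low,ci_high,R`.
#'
#' @param agg an `aggregated_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_aggregated_csv <- function(agg, path) {
  utils::write.csv(agg, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce the directory bit-identically with
#' the same package version: the resolved config, the master and per-replicate
#' seeds, and the realized network metadata.
#'
#' @param out_dir output directory.
#' @param cfg the `sim_config` used.
#' @param seeds integer vector of per-replicate (or per-cell) seeds.
#' @param net the `interaction_network` used, or `NULL`.
#' @param extra optional named list merged into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, cfg, seeds, net = NULL, extra = list()) {
  cfg_echo <- cfg[c("N", "S", "m", "mu", "timesteps", "A0", "R", "seed",
                    "stat_interval")]
  manifest <- c(list(
    package = "netdrift",
    version = as.character(utils::packageVersion("netdrift")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = cfg_echo,
    master_seed = cfg$seed,
    seeds = as.integer(seeds)
  ), extra)
  if (!is.null(net)) {
    mx <- network_metrics(net)
    manifest$network <- list(builder = net$builder, params = net$params,
                             n_nodes = net$n_nodes,
                             mean_degree = mx$mean_degree,
                             n_components = mx$n_components)
  }
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
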