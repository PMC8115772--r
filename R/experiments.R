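# Orchestration: replicate runs, parameter sweeps and preset experiment
# families, with tidy CSV outputs.

#' Run all replicates of one simulation condition
#'
#' Runs `cfg$R` replicates of a condition, each with its own seed derived from
#' the master seed via [derive_seed()], and aggregates them into mean and
#' confidence bands. When `out_dir` is given, per-replicate and aggregated
#' series plus a run manifest are written there.
#'
#' @param cfg a [sim_config()].
#' @param net an `interaction_network` (or `NULL` to build from
#'   `cfg$network`).
#' @param out_dir optional output directory.
#' @param ci `"t"` or `"percentile"` confidence bands.
#' @return A list with `replicates` (list of `stat_series`), `aggregated`
#'   (an `aggregated_series`) and `seeds`.
#' @export
run_condition <- function(cfg, net = NULL, out_dir = NULL, ci = "t") {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(net)) {
    if (is.null(cfg$network) && (cfg$m == 0 || cfg$S == 1)) {
      net <- NULL
    } else {
      net <- build_network(cfg$network, S = cfg$S)
    }
  }
  seeds <- derive_seed(cfg$seed, seq_len(cfg$R))
  reps <- lapply(seeds, function(s) run_replicate(cfg, net, replicate_seed = s))
  agg <- aggregate_replicates(reps, method = ci)
  res <- list(replicates = reps, aggregated = agg, seeds = seeds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_series_csv(reps, file.path(out_dir, "condition.csv"))
    write_aggregated_csv(agg, file.path(out_dir, "condition_aggregated.csv"))
    if (!is.null(net)) write_network(net, file.path(out_dir, "network"))
    write_manifest(out_dir, cfg, seeds, net)
  }
  invisible(res)
}

#' Final-time statistics over a parameter grid
#'
#' Crosses the supplied axis vectors (any of `k`, `m`, `S`) into a grid of
#' conditions, runs `cfg$R` replicates per cell with per-cell derived seeds,
#' and records the final-time mean and confidence interval of every tracked
#' statistic. The network is rebuilt per cell whenever `k` or `S` varies,
#' using the builder family in `base_cfg$network` (ring/small-world by
#' default; spatial kNN when the base spec says so). Infeasible cells (e.g.
#' `k >= S`) are marked invalid and skipped, not errors.
#'
#' @param base_cfg a [sim_config()] providing all non-swept parameters; its
#'   `network` field must be a builder spec (not a fixed network) when `k` or
#'   `S` is swept.
#' @param axes named list of parameter vectors; names among `k`, `m`, `S`.
#' @param out_dir optional output directory for `sweep.csv` and a manifest.
#' @return A `sweep_grid` data frame: one row per cell with the axis values,
#'   `valid`, `cell_seed`, `R`, `T_final` and `<stat>_mean`, `<stat>_lo`,
#'   `<stat>_hi` columns.
#' @export
run_sweep <- function(base_cfg, axes, out_dir = NULL) {
  stopifnot(inherits(base_cfg, "sim_config"))
  if (!length(axes) || is.null(names(axes)) ||
      !all(names(axes) %in% c("k", "m", "S"))) {
    stop("axes must be a named list with names among 'k', 'm', 'S'")
  }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  stats_names <- c("fst", "richness", "unique_trait_subpops", "heterozygosity")
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cell <- as.list(grid[i, , drop = FALSE])
    S_i <- if (!is.null(cell$S)) as.integer(cell$S) else base_cfg$S
    m_i <- if (!is.null(cell$m)) cell$m else base_cfg$m
    spec <- base_cfg$network %||% list(type = "small_world", k = 2, p_rewire = 0)
    if (inherits(spec, "interaction_network")) {
      if (!is.null(cell$k) || !is.null(cell$S)) {
        stop("sweeping k or S requires a network builder spec, not a fixed network")
      }
      net <- spec
      valid <- TRUE
    } else {
      if (!is.null(cell$k)) spec$k <- as.integer(cell$k)
      kmax <- if (identical(spec$type, "spatial_knn")) S_i - 1L else S_i - 1L
      valid <- is.null(spec$k) || (spec$k >= if (identical(spec$type, "spatial_knn")) 1L else 2L) && spec$k <= kmax
      net <- NULL
    }
    cell_seed <- derive_seed(base_cfg$seed, i)
    row <- data.frame(cell, valid = valid, cell_seed = cell_seed,
                      R = base_cfg$R, T_final = base_cfg$timesteps)
    if (valid) {
      cfg_i <- sim_config(N = base_cfg$N, S = S_i, m = m_i, mu = base_cfg$mu,
                          timesteps = base_cfg$timesteps,
                          A0 = min(base_cfg$A0, base_cfg$N %/% S_i),
                          R = base_cfg$R, seed = cell_seed,
                          stat_interval = base_cfg$timesteps)
      if (is.null(net)) {
        spec$seed <- spec$seed %||% cell_seed
        net <- tryCatch(build_network(spec, S = S_i), error = function(e) NULL)
      }
      if (is.null(net) && (m_i > 0 && S_i > 1)) {
        row$valid <- FALSE
        valid <- FALSE
      }
    }
    if (valid) {
      res <- run_condition(cfg_i, net)
      fin <- res$aggregated[res$aggregated$timestep == cfg_i$timesteps, ]
      for (st in stats_names) {
        fr <- fin[fin$statistic == st, ]
        row[[paste0(st, "_mean")]] <- fr$mean
        row[[paste0(st, "_lo")]] <- fr$ci_low
        row[[paste0(st, "_hi")]] <- fr$ci_high
      }
    } else {
      for (st in stats_names) {
        row[[paste0(st, "_mean")]] <- NA_real_
        row[[paste0(st, "_lo")]] <- NA_real_
        row[[paste0(st, "_hi")]] <- NA_real_
      }
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_grid", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "sweep.csv"), row.names = FALSE)
    write_manifest(out_dir, base_cfg, out$cell_seed, NULL,
                   extra = list(axes = axes))
  }
  out
}

# thin a vector to roughly `scale` of its points, always keeping endpoints
thin_axis <- function(v, scale) {
  if (scale >= 1 || length(v) <= 2) return(v)
  step <- ceiling(1 / scale)
  idx <- unique(c(seq(1, length(v), by = step), length(v)))
  v[idx]
}

log_spaced <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

#' Preset experiment configurations
#'
#' Returns the configuration of one of the package's canonical experiment
#' families without running it. Families `fig3_4` and `fig5_6` are time-series
#' comparisons (connectivity `k = 2, 50, 120` at `S = 200`; subpopulation
#' count `S = 20, 50, 200` at `k = 2`); `fig7_8` and `fig11_12` sweep ring
#' connectivity `k = 5..190` (step 5) against between-group interaction rates
#' spanning `1e-4` to `5e-3`; `fig9_10` sweeps subpopulation count against the
#' same rates at `k = 2`; the `rapanui` families place 150 communities on a
#' synthetic island coastline and connect them by spatial k-nearest-neighbour
#' interaction (`k = 5, 50, 140` series, or a `k x m` sweep). The island
#' series uses a deliberately low interaction rate (`m = 1e-4`).
#'
#' `scale` thins replicate counts and sweep-grid density for desk-scale runs;
#' it never changes the model parameters of a condition (N, S, m, mu, T).
#'
#' @param name one of `fig3_4`, `fig5_6`, `fig7_8`, `fig9_10`, `fig11_12`,
#'   `rapanui_14_15`, `rapanui_16_17`.
#' @param scale fraction in `(0, 1]` multiplying R and the grid density.
#' @param seed master seed.
#' @return A list with `name`, `type` (`"series"` or `"sweep"`), and either
#'   `conditions` (a list of `(label, cfg, network_spec)` triples) or
#'   `base_cfg` + `axes`.
#' @export
preset_config <- function(name, scale = 1, seed = 1L) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  sc_R <- function(R) max(1L, as.integer(round(R * scale)))
  series <- function(labels, cfgs, specs) {
    list(name = name, type = "series",
         conditions = Map(function(l, c, s) list(label = l, cfg = c, network_spec = s),
                          labels, cfgs, specs))
  }
  m_axis <- thin_axis(log_spaced(1e-4, 5e-3, 10), scale)
  switch(
    name,
    fig3_4 = {
      ks <- c(2L, 50L, 120L)
      cfgs <- lapply(ks, function(k) sim_config(
        N = 5000, S = 200, m = 0.0025, mu = 0, timesteps = 2000,
        R = sc_R(10), seed = derive_seed(seed, k), stat_interval = 50L))
      specs <- lapply(ks, function(k) list(type = "small_world", k = k,
                                           p_rewire = 0, seed = seed))
      series(paste0("k=", ks), cfgs, specs)
    },
    fig5_6 = {
      Ss <- c(20L, 50L, 200L)
      # common A0 across conditions so every configuration starts with the
      # same richness (floor(N / max(S)) fits the smallest subpopulation)
      cfgs <- lapply(Ss, function(S) sim_config(
        N = 5000, S = S, m = 0.0025, mu = 0, timesteps = 5000, A0 = 25L,
        R = sc_R(10), seed = derive_seed(seed, S), stat_interval = 50L))
      specs <- lapply(Ss, function(S) list(type = "small_world", k = 2L,
                                           p_rewire = 0, seed = seed))
      series(paste0("S=", Ss), cfgs, specs)
    },
    fig7_8 = ,
    fig11_12 = list(
      name = name, type = "sweep",
      base_cfg = sim_config(N = 5000, S = 200, mu = 0, timesteps = 2000,
                            R = sc_R(10), seed = seed,
                            network = list(type = "small_world", p_rewire = 0)),
      axes = list(k = thin_axis(seq(5L, 190L, by = 5L), scale), m = m_axis)
    ),
    fig9_10 = list(
      name = name, type = "sweep",
      base_cfg = sim_config(N = 5000, S = 200, mu = 0, timesteps = 2000,
                            R = sc_R(10), seed = seed,
                            network = list(type = "small_world", k = 2L,
                                           p_rewire = 0)),
      axes = list(S = thin_axis(c(5L, 10L, 20L, 50L, 100L, 150L, 200L), scale),
                  m = m_axis)
    ),
    rapanui_14_15 = {
      ks <- c(5L, 50L, 140L)
      cfgs <- lapply(ks, function(k) sim_config(
        N = 5000, S = 150, m = 1e-4, mu = 0, timesteps = 2000,
        R = sc_R(10), seed = derive_seed(seed, k), stat_interval = 50L))
      specs <- lapply(ks, function(k) list(type = "spatial_knn", k = k,
                                           n_points = 150L, seed = seed))
      series(paste0("k=", ks), cfgs, specs)
    },
    rapanui_16_17 = list(
      name = name, type = "sweep",
      base_cfg = sim_config(N = 5000, S = 150, mu = 0, timesteps = 2000,
                            R = sc_R(10), seed = seed,
                            network = list(type = "spatial_knn",
                                           n_points = 150L, seed = seed)),
      axes = list(k = thin_axis(c(5L, 20L, 50L, 80L, 110L, 140L), scale),
                  m = m_axis)
    ),
    stop(sprintf("unknown preset '%s'", name))
  )
}

#' Run a preset experiment family
#'
#' Builds the preset via [preset_config()] and executes it: a series preset
#' runs each condition with [run_condition()]; a sweep preset runs
#' [run_sweep()]. Outputs are written under `out_dir` when given.
#'
#' @inheritParams preset_config
#' @param out_dir optional output directory.
#' @return For a series preset, a named list of [run_condition()] results;
#'   for a sweep preset, a `sweep_grid`.
#' @export
run_preset <- function(name, scale = 1, seed = 1L, out_dir = NULL) {
  pc <- preset_config(name, scale = scale, seed = seed)
  if (pc$type == "series") {
    res <- lapply(pc$conditions, function(cond) {
      net <- build_network(cond$network_spec, S = cond$cfg$S)
      dir_i <- if (!is.null(out_dir)) file.path(out_dir, cond$label)
      run_condition(cond$cfg, net, out_dir = dir_i)
    })
    names(res) <- vapply(pc$conditions, `[[`, character(1), "label")
    res
  } else {
    run_sweep(pc$base_cfg, pc$axes, out_dir = out_dir)
  }
}
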