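# Differentiation and richness statistics, and replicate aggregation.

#' Per-subpopulation trait frequency table
#'
#' Tabulates exact integer-count frequencies of every trait label present
#' anywhere in the population, per subpopulation, together with the
#' subpopulation size shares and the size-weighted global frequency of each
#' label (the mean frequency `p` of the trait in the total population).
#'
#' @param pop a `trait_population`.
#' @return A list of class `frequency_table` with `labels` (distinct labels,
#'   ascending), `freq` (an `S x L` matrix of within-subpopulation
#'   frequencies), `counts` (the corresponding integer counts), `weights`
#'   (`n_s / N`) and `global_freq` (length `L`).
#' @export
trait_frequencies <- function(pop) {
  labels <- sort(unique(pop$traits))
  L <- length(labels)
  S <- length(pop$subpop_sizes)
  lab_idx <- match(pop$traits, labels)
  counts <- matrix(
    tabulate(pop$subpop_of + S * (lab_idx - 1L), nbins = S * L),
    nrow = S, ncol = L
  )
  freq <- counts / pop$subpop_sizes
  w <- pop$subpop_sizes / sum(pop$subpop_sizes)
  ft <- list(labels = labels, freq = freq, counts = counts, weights = w,
             global_freq = as.numeric(colSums(counts) / sum(pop$subpop_sizes)))
  class(ft) <- "frequency_table"
  ft
}

#' Fixation index F_ST over trait labels
#'
#' Wright's fixation index measures differentiation of subpopulations: the
#' variance of a trait's frequency between subpopulations relative to the
#' total-population term `p (1 - p)`. For each label `a` present, the
#' size-weighted between-subpopulation variance is
#' `sigma2_a = sum_s w_s (f_sa - p_a)^2` with `w_s = n_s / N`, and the
#' multi-label statistic aggregates as a ratio of sums,
#' `F_ST = sum_a sigma2_a / sum_a p_a (1 - p_a)`, which reduces to the
#' single-trait form in the biallelic case. Globally fixed labels contribute
#' zero to both sums; a population where every individual carries the same
#' label (denominator zero) returns 0, the value for identical
#' subpopulations. The result always lies in `[0, 1]`: 0 when all
#' subpopulations have identical trait distributions, 1 when subpopulations
#' are completely differentiated.
#'
#' @param x a `frequency_table` or a `trait_population`.
#' @return F_ST in `[0, 1]`.
#' @export
fst <- function(x) {
  ft <- if (inherits(x, "frequency_table")) x else trait_frequencies(x)
  p <- ft$global_freq
  dev <- sweep(ft$freq, 2, p)
  sigma2 <- as.numeric(ft$weights %*% dev^2)
  denom <- sum(p * (1 - p))
  if (denom <= 0) return(0)
  min(1, max(0, sum(sigma2) / denom))
}

#' Trait richness
#'
#' The number of distinct trait labels present across all individuals.
#'
#' @param pop a `trait_population`.
#' @return Integer count, at least 1.
#' @export
richness <- function(pop) {
  length(unique(pop$traits))
}

#' Number of subpopulations holding a private trait
#'
#' Counts the subpopulations that possess at least one trait label found in
#' no other subpopulation -- the rare-trait retention measure.
#'
#' @param pop a `trait_population`.
#' @return Integer in `[0, S]`.
#' @export
unique_trait_subpops <- function(pop) {
  ft <- trait_frequencies(pop)
  present <- ft$counts > 0L
  private <- colSums(present) == 1L
  if (!any(private)) return(0L)
  sum(rowSums(present[, private, drop = FALSE]) > 0L)
}

#' Population heterozygosity
#'
#' The probability that two individuals drawn uniformly (with replacement,
#' ignoring subpopulation structure) carry different trait labels:
#' `1 - sum_a (count_a / N)^2`.
#'
#' @param pop a `trait_population`.
#' @return A value in `[0, 1]`.
#' @export
heterozygosity <- function(pop) {
  p <- tabulate(match(pop$traits, unique(pop$traits))) / length(pop$traits)
  1 - sum(p^2)
}

stat_ranges <- list(
  fst = c(0, 1),
  richness = c(1, Inf),
  unique_trait_subpops = c(0, Inf),
  heterozygosity = c(0, 1)
)

#' Aggregate replicate series into mean and confidence bands
#'
#' Aligns a list of replicate [run_replicate()] series on their common
#' snapshot grid and computes, per timestep and statistic, the sample mean
#' with either a Student-t confidence interval
#' (`mean +/- t_{R-1, (1+level)/2} * sd / sqrt(R)`) or a percentile interval
#' across replicates. Bands are clipped to each statistic's valid range. With
#' a single replicate the bands collapse to the mean and the result is
#' flagged degenerate.
#'
#' @param series a list of `stat_series` sharing the same snapshot timesteps.
#' @param level confidence level, default 0.95.
#' @param method `"t"` (default) or `"percentile"`.
#' @return An `aggregated_series` data frame in long format with columns
#'   `timestep`, `statistic`, `mean`, `ci_low`, `ci_high`, `R`, with
#'   attribute `degenerate = TRUE` when `R = 1`.
#' @export
aggregate_replicates <- function(series, level = 0.95,
                                 method = c("t", "percentile")) {
  method <- match.arg(method)
  if (inherits(series, "stat_series")) series <- list(series)
  R <- length(series)
  if (R < 1) stop("need at least one replicate series")
  ts0 <- series[[1]]$timestep
  for (s in series) {
    if (!identical(s$timestep, ts0)) {
      stop("replicate series have mismatched snapshot timesteps and cannot be aligned")
    }
  }
  stats_names <- c("fst", "richness", "unique_trait_subpops", "heterozygosity")
  out <- list()
  for (st in stats_names) {
    vals <- vapply(series, function(s) as.numeric(s[[st]]),
                   numeric(length(ts0)))
    vals <- matrix(vals, nrow = length(ts0))
    mu <- rowMeans(vals)
    if (R == 1) {
      lo <- hi <- mu
    } else if (method == "t") {
      se <- apply(vals, 1, stats::sd) / sqrt(R)
      q <- stats::qt((1 + level) / 2, df = R - 1)
      lo <- mu - q * se
      hi <- mu + q * se
    } else {
      a <- (1 - level) / 2
      lo <- apply(vals, 1, stats::quantile, probs = a, names = FALSE)
      hi <- apply(vals, 1, stats::quantile, probs = 1 - a, names = FALSE)
    }
    rng <- stat_ranges[[st]]
    lo <- pmin(pmax(lo, rng[1]), rng[2])
    hi <- pmin(pmax(hi, rng[1]), rng[2])
    out[[st]] <- data.frame(timestep = ts0, statistic = st, mean = mu,
                            ci_low = lo, ci_high = hi, R = R)
  }
  agg <- do.call(rbind, out)
  rownames(agg) <- NULL
  attr(agg, "level") <- level
  attr(agg, "method") <- method
  attr(agg, "degenerate") <- R == 1
  class(agg) <- c("aggregated_series", "data.frame")
  agg
}
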