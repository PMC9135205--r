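#' Linear-ramp target pattern
#'
#' Target time course in which every gene's abundance increases linearly,
#' `Y_k(t) = slope_k * t`. Slopes must be non-negative and not all zero:
#' a gene with zero mean target abundance would make the normalized RMSE
#' undefined.
#'
#' @param slopes Named or unnamed numeric vector of per-gene slopes
#'   (abundance units per second).
#' @param times Sampling grid, e.g. `seq(0, 300, by = 5)`.
#' @param genes Gene names; defaults to the names of `slopes` or
#'   `gene1..geneK`.
#' @return An `expression_time_course` usable as a target pattern.
#' @export
make_linear_pattern <- function(slopes, times = seq(0, 300, by = 5),
                                genes = NULL) {
  if (any(slopes < 0)) stop("slopes must be non-negative")
  if (all(slopes == 0))
    stop("at least one slope must be positive (zero mean target abundance)")
  genes <- pattern_gene_names(slopes, genes)
  y <- outer(times, slopes)
  colnames(y) <- genes
  time_course(times, y)
}

#' Ramp-then-plateau target pattern
#'
#' Piecewise-linear target: gene k increases at `slope_k` until
#' `breakpoint_k` seconds, then stays constant at `slope_k * breakpoint_k`.
#' A breakpoint at or beyond the end of the grid gives a pure linear ramp;
#' per-gene (slope, breakpoint) choices create plateaus at different levels
#' and cross-over patterns where the abundance ordering of genes changes
#' over time.
#'
#' @param slopes Per-gene slopes (non-negative, not all zero).
#' @param breakpoints Per-gene plateau onset times in seconds
#'   (non-negative; `Inf` for no plateau). Recycled to the length of
#'   `slopes`.
#' @param times Sampling grid.
#' @param genes Gene names.
#' @return An `expression_time_course`.
#' @export
make_plateau_pattern <- function(slopes, breakpoints,
                                 times = seq(0, 300, by = 5), genes = NULL) {
  if (any(slopes < 0)) stop("slopes must be non-negative")
  if (any(breakpoints < 0)) stop("breakpoints must be non-negative")
  breakpoints <- rep_len(breakpoints, length(slopes))
  if (all(slopes == 0))
    stop("at least one slope must be positive (zero mean target abundance)")
  genes <- pattern_gene_names(slopes, genes)
  y <- vapply(seq_along(slopes),
              function(k) slopes[k] * pmin(times, breakpoints[k]),
              numeric(length(times)))
  colnames(y) <- genes
  time_course(times, y)
}

pattern_gene_names <- function(slopes, genes) {
  if (is.null(genes)) genes <- names(slopes)
  if (is.null(genes)) genes <- paste0("gene", seq_along(slopes))
  genes
}

#' Positive-control target from a known architecture
#'
#' Simulates a known genome architecture and re-labels the replicate-mean
#' time course as a target pattern. Because the generating architecture is
#' known, at least one exact solution to the target is guaranteed to exist,
#' which makes these targets the natural positive control for the
#' evolutionary engine.
#'
#' @param genome The generating `genome_architecture`; must contain at
#'   least one promoter so every gene has positive mean target abundance.
#' @param config A `simulation_config`.
#' @param n_replicates Replicates averaged into the target (default 10).
#' @param seed Master seed for reproducibility.
#' @return An `expression_time_course` target.
#' @export
make_positive_control <- function(genome, config = simulation_config(),
                                  n_replicates = 10, seed = NULL) {
  if (!any(genome$elements$kind == "promoter"))
    stop("genome has no promoter: all target abundances would be zero")
  tgt <- simulate_replicates(genome, config, n = n_replicates, seed = seed)
  if (any(colMeans(tc_matrix(tgt)) <= 0))
    stop("positive-control target has a gene with zero mean abundance; ",
         "use a stronger promoter, more replicates, or a longer horizon")
  tgt
}

#' Named library of approximate target patterns
#'
#' Ten parametric three-gene target patterns spanning the qualitative
#' classes studied with this tool: linear ramps at equal or differing
#' rates, plateaus at different levels indicating a steady-state balance of
#' production and degradation, and cross-over patterns where the relative
#' abundance ordering of genes changes over time. The presets are
#' approximations of those qualitative shapes, not reconstructions of any
#' specific published target values.
#'
#' @param name Preset name; see `names(target_presets())`. If `NULL`,
#'   returns the list of all preset generator descriptions.
#' @param times Sampling grid.
#' @return An `expression_time_course` (or, with `name = NULL`, a named
#'   list of parameter sets).
#' @export
target_preset <- function(name = NULL, times = seq(0, 300, by = 5)) {
  presets <- target_presets()
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset `", name, "`; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  make_plateau_pattern(p$slopes, p$breakpoints, times = times)
}

#' @rdname target_preset
#' @export
target_presets <- function() {
  list(
    `linear-equal`          = list(slopes = c(0.10, 0.10, 0.10),
                                   breakpoints = c(Inf, Inf, Inf)),
    `linear-distinct`       = list(slopes = c(0.20, 0.10, 0.05),
                                   breakpoints = c(Inf, Inf, Inf)),
    `linear-reversed`       = list(slopes = c(0.05, 0.10, 0.20),
                                   breakpoints = c(Inf, Inf, Inf)),
    `one-plateau`           = list(slopes = c(0.20, 0.10, 0.05),
                                   breakpoints = c(150, Inf, Inf)),
    `plateaus-distinct`     = list(slopes = c(0.30, 0.20, 0.10),
                                   breakpoints = c(100, 150, 200)),
    `plateaus-equal-level`  = list(slopes = c(0.30, 0.15, 0.10),
                                   breakpoints = c(100, 200, 300)),
    `staggered-plateaus`    = list(slopes = c(0.40, 0.20, 0.10),
                                   breakpoints = c(50, 150, 250)),
    `crossover-single`      = list(slopes = c(0.30, 0.10, 0.05),
                                   breakpoints = c(100, Inf, Inf)),
    `crossover-double`      = list(slopes = c(0.40, 0.15, 0.08),
                                   breakpoints = c(60, 160, Inf)),
    `crossover-late`        = list(slopes = c(0.20, 0.12, 0.30),
                                   breakpoints = c(120, Inf, 80))
  )
}
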