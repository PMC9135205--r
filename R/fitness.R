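#' Per-gene RMSE between observed and target time courses
#'
#' Root-mean-square error for gene k over the shared time grid:
#' `RMSE_k = sqrt( sum_t (y_k(t) - Y_k(t))^2 / T )`, with T the number of
#' sampled time points.
#'
#' @param observed,target `expression_time_course` objects on the same
#'   grid with the same gene set.
#' @param gene Gene name or column index.
#' @return Non-negative scalar.
#' @export
rmse_per_gene <- function(observed, target, gene) {
  check_grids(observed, target)
  y <- tc_matrix(observed)[, gene]
  Y <- tc_matrix(target)[, gene]
  sqrt(sum((y - Y)^2) / length(Y))
}

check_grids <- function(observed, target) {
  if (nrow(observed) != nrow(target) ||
      any(abs(observed$time - target$time) > 1e-9))
    stop("observed and target time grids do not match")
  if (!setequal(tc_genes(observed), tc_genes(target)))
    stop("observed and target gene sets do not match")
  invisible(TRUE)
}

#' Normalized RMSE between a simulated and a target expression pattern
#'
#' Each gene's RMSE is divided by M times its mean target abundance
#' `Ybar_k = sum_t Y_k(t) / T` and the terms are summed over the M genes:
#' `RMSE_norm = sum_k RMSE_k / (M * Ybar_k)`. The statistic is
#' scale-free: jointly rescaling observed and target values leaves it
#' unchanged. A run is conventionally called successful when
#' `RMSE_norm <= 0.1` (see [is_successful()]).
#'
#' @param observed,target `expression_time_course` objects on the same
#'   grid with the same gene set; every target gene must have positive
#'   mean abundance.
#' @return Non-negative scalar.
#' @export
normalized_rmse <- function(observed, target) {
  check_grids(observed, target)
  genes <- tc_genes(target)
  Ybar <- colMeans(tc_matrix(target))[genes]
  if (any(Ybar <= 0))
    stop("normalization undefined: zero mean target abundance for gene(s) ",
         paste(genes[Ybar <= 0], collapse = ", "))
  m <- length(genes)
  sum(vapply(genes, function(g) rmse_per_gene(observed, target, g) /
               (m * Ybar[g]), 0))
}

#' Fitness specification
#'
#' Chooses how the normalized RMSE distance r maps to fitness f:
#' * `fermi`: `f = 1 / (exp(beta * r) + 1)` — equals 1/2 at r = 0 and
#'   declines monotonically to 0;
#' * `exponential`: `f = exp(-beta * r)`;
#' * `linear`: `f = -beta * r` (non-positive; the origin-fixation ratio is
#'   then taken after adding `offset`, see [acceptance_probability()]).
#'
#' `beta` sets the strength of selection and is typically driven by the
#' annealing schedule during evolution.
#'
#' @param fun One of `"fermi"`, `"exponential"`, `"linear"`.
#' @param beta Selection strength, >= 0.
#' @param offset Positive shift applied to linear fitness values before
#'   forming fitness ratios (default 1); ignored for the other functions.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(fun = c("fermi", "exponential", "linear"),
                         beta = 1, offset = 1) {
  fun <- match.arg(fun)
  if (!is.numeric(beta) || beta < 0) stop("`beta` must be >= 0")
  if (fun == "linear" && offset <= 0)
    stop("`offset` must be positive for linear fitness")
  structure(list(fun = fun, beta = beta, offset = offset),
            class = "fitness_spec")
}

#' Map a normalized RMSE to fitness
#'
#' @param rmse_norm Non-negative distance between simulated and target
#'   patterns.
#' @param spec A [fitness_spec()].
#' @return Scalar fitness value.
#' @export
fitness_of <- function(rmse_norm, spec = fitness_spec()) {
  if (any(rmse_norm < 0)) stop("`rmse_norm` must be non-negative")
  switch(spec$fun,
         fermi = 1 / (exp(spec$beta * rmse_norm) + 1),
         exponential = exp(-spec$beta * rmse_norm),
         linear = -spec$beta * rmse_norm,
         stop("unknown fitness function: ", spec$fun))
}

#' Success criterion for an evolved pattern
#'
#' A solution counts as successful when its replicate-averaged normalized
#' RMSE does not exceed the threshold (inclusive; default 0.1).
#'
#' @param rmse_norm Non-negative normalized RMSE.
#' @param threshold Success cut-off (default 0.1).
#' @return Logical.
#' @export
is_successful <- function(rmse_norm, threshold = 0.1) {
  if (any(rmse_norm < 0)) stop("`rmse_norm` must be non-negative")
  rmse_norm <= threshold
}
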