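#' Census of architecture fingerprints
#'
#' Counts the occurrences of each unique architecture fingerprint among a
#' set of evolved solutions. Only successful solutions (normalized RMSE at
#' or below the threshold) should be included; if `rmse_norm` values are
#' supplied, unsuccessful entries are dropped here.
#'
#' @param fingerprints Character vector of fingerprints (see
#'   [fingerprint()]), or a list of `genome_architecture` objects.
#' @param rmse_norm Optional numeric vector of per-solution normalized RMSE
#'   values used to filter to successful solutions.
#' @param threshold Success cut-off (default 0.1).
#' @return An `architecture_census`: data frame with columns `fingerprint`
#'   and `count`, plus attribute `n` (total solutions counted).
#' @export
architecture_census <- function(fingerprints, rmse_norm = NULL,
                                threshold = 0.1) {
  if (is.list(fingerprints))
    fingerprints <- vapply(fingerprints, fingerprint, "")
  if (!is.null(rmse_norm)) {
    if (length(rmse_norm) != length(fingerprints))
      stop("`rmse_norm` must match `fingerprints` in length")
    fingerprints <- fingerprints[is_successful(rmse_norm, threshold)]
  }
  if (length(fingerprints) == 0)
    stop("census is empty: no successful solutions")
  tab <- table(fingerprints)
  census <- data.frame(fingerprint = names(tab),
                       count = as.integer(tab),
                       stringsAsFactors = FALSE)
  census <- census[order(-census$count, census$fingerprint), , drop = FALSE]
  rownames(census) <- NULL
  structure(census, n = sum(census$count),
            class = c("architecture_census", "data.frame"))
}

#' Shannon entropy of an architecture census
#'
#' Diversity of a set of evolved genome architectures, in bits:
#' `H = -sum_i (n_i / n) * log2(n_i / n)` over the counts `n_i` of each
#' unique fingerprint. H = 0 when every solution shares one architecture;
#' H = log2(u) when u unique architectures occur equally often, so an
#' entropy of 1 corresponds to effectively 2 distinct architectures and an
#' entropy of 5 to effectively 32.
#'
#' @param census An `architecture_census`, or anything accepted by
#'   [architecture_census()].
#' @return Entropy in bits.
#' @export
architecture_entropy <- function(census) {
  if (!inherits(census, "architecture_census"))
    census <- architecture_census(census)
  if (nrow(census) == 0) stop("census is empty")
  p <- census$count / sum(census$count)
  -sum(p * log2(p))
}
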