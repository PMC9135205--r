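#' Greedy removal of regulatory elements with negligible effect
#'
#' Element strengths are free to evolve toward values so small that the
#' element no longer does anything. To compare evolved architectures
#' fairly, such passengers are pruned after evolution: each element is
#' removed in turn and the genome re-evaluated against the target; every
#' removal that keeps the replicate-averaged normalized RMSE at or below
#' the success threshold marks a candidate, the candidate whose removal has
#' the least impact is removed, and the process repeats until no element
#' can be removed without breaking the threshold. The procedure is greedy
#' and deliberately ignores epistatic interactions between elements.
#'
#' @param genome A successful `genome_architecture` (its own evaluation
#'   must satisfy the threshold, otherwise an error is raised).
#' @param target Target `expression_time_course`.
#' @param sim_config A [simulation_config()].
#' @param replicates Replicates per evaluation (default 10).
#' @param threshold Success cut-off (default 0.1).
#' @param criterion `"post_rmse"` (default) removes the candidate with the
#'   smallest post-removal normalized RMSE; `"delta"` removes the candidate
#'   whose removal changes the RMSE the least relative to the current
#'   genome.
#' @param seed Master seed; every candidate evaluation draws a fresh
#'   derived seed.
#' @return List with `genome` (the pruned architecture) and `log` — a data
#'   frame of the removals in order (step, kind, region, strength,
#'   rmse_after).
#' @export
prune_genome <- function(genome, target, sim_config = simulation_config(),
                         replicates = 10, threshold = 0.1,
                         criterion = c("post_rmse", "delta"), seed = NULL) {
  criterion <- match.arg(criterion)
  with_seed(seed, {
    evaluate <- function(g) {
      s <- sample.int(.Machine$integer.max, 1)
      normalized_rmse(
        simulate_replicates(g, sim_config, n = replicates, seed = s), target)
    }
    current_rmse <- evaluate(genome)
    if (!is_successful(current_rmse, threshold))
      stop(sprintf(
        "genome is not successful (rmse_norm %.4f > %.4f); nothing to prune",
        current_rmse, threshold))

    log <- data.frame(step = integer(), kind = character(),
                      region = integer(), strength = numeric(),
                      rmse_after = numeric())
    step <- 0L
    repeat {
      el <- genome$elements
      if (nrow(el) == 0) break
      # elements in (region, kind) order for deterministic tie-breaking
      cand_rmse <- rep(NA_real_, nrow(el))
      for (i in seq_len(nrow(el))) {
        g2 <- remove_element(genome, el$kind[i], el$region[i])
        cand_rmse[i] <- evaluate(g2)
      }
      score <- switch(criterion,
                      post_rmse = cand_rmse,
                      delta = abs(cand_rmse - current_rmse))
      ok <- is_successful(cand_rmse, threshold)
      if (!any(ok)) break
      score[!ok] <- Inf
      i <- which.min(score)  # first minimum wins ties
      step <- step + 1L
      log <- rbind(log, data.frame(step = step, kind = el$kind[i],
                                   region = el$region[i],
                                   strength = el$strength[i],
                                   rmse_after = cand_rmse[i]))
      genome <- remove_element(genome, el$kind[i], el$region[i])
      current_rmse <- cand_rmse[i]
    }
    list(genome = genome, log = log, rmse_norm = current_rmse)
  })
}
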