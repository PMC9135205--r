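#' Enumerate all possible mutations of a genome architecture
#'
#' The mutational neighbourhood of a genotype: one `add` for every empty
#' (kind, region) slot, and one `remove` and one `modify` for every
#' existing regulatory element. With M genes there are 3 * (M + 1) slots,
#' so a genome carrying E elements has `3 * (M + 1) - E` additions, E
#' removals and E modifications.
#'
#' @param genome A `genome_architecture`.
#' @return Data frame with columns `action`, `kind`, `region`, one row per
#'   possible mutation, in deterministic order (adds by region then kind,
#'   then removes, then modifies).
#' @export
enumerate_mutations <- function(genome) {
  m <- n_genes(genome)
  slots <- expand.grid(kind = element_kinds(), region = 0:m,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(slots$kind, slots$region)
  occupied <- paste(genome$elements$kind, genome$elements$region)
  adds <- slots[!key %in% occupied, , drop = FALSE]
  el <- genome$elements
  out <- rbind(
    if (nrow(adds) > 0)
      data.frame(action = "add", kind = adds$kind, region = adds$region),
    if (nrow(el) > 0)
      data.frame(action = "remove", kind = el$kind, region = el$region),
    if (nrow(el) > 0)
      data.frame(action = "modify", kind = el$kind, region = el$region)
  )
  rownames(out) <- NULL
  out
}

#' Multiplicative strength modification
#'
#' Draws a multiplier from Normal(mean = 1, sd = 0.1) and multiplies the
#' current strength by it. If the product falls outside the kind's bounds
#' the draw is discarded and repeated until a valid value results. Consumes
#' one normal deviate per attempt from the current RNG stream.
#'
#' @param strength Current element strength.
#' @param bounds List with `min` and `max` components.
#' @param sd Standard deviation of the multiplier distribution
#'   (default 0.1).
#' @return List with `strength` (the new value), `multiplier` (the accepted
#'   draw) and `n_draws` (total draws including discarded ones).
#' @export
modify_strength <- function(strength, bounds, sd = 0.1) {
  n_draws <- 0L
  repeat {
    mult <- stats::rnorm(1, mean = 1, sd = sd)
    n_draws <- n_draws + 1L
    new <- strength * mult
    if (new >= bounds$min && new <= bounds$max)
      return(list(strength = new, multiplier = mult, n_draws = n_draws))
    if (n_draws > 10000L)
      stop("could not draw an in-bounds strength modification")
  }
}

#' Apply a mutation to a genome
#'
#' @param genome A `genome_architecture`.
#' @param mutation List or one-row data frame with `action`, `kind`,
#'   `region`, and for `modify` a `multiplier`.
#' @param defaults Element defaults (insertion strengths and bounds).
#' @return The mutated `genome_architecture`.
#' @export
apply_mutation <- function(genome, mutation, defaults = element_defaults()) {
  switch(as.character(mutation$action),
         add = add_element(genome, mutation$kind, mutation$region,
                           defaults[[mutation$kind]]$insert, defaults),
         remove = remove_element(genome, mutation$kind, mutation$region),
         modify = {
           idx <- element_index(genome, mutation$kind, mutation$region)
           new <- genome$elements$strength[idx] * mutation$multiplier
           set_element_strength(genome, mutation$kind, mutation$region, new,
                                defaults)
         },
         stop("unknown mutation action: ", mutation$action))
}

#' Propose one random mutation
#'
#' Draws uniformly from [enumerate_mutations()] and applies it: additions
#' insert the kind's default strength, modifications multiply the current
#' strength by a Normal(1, 0.1) draw, redrawing out-of-bounds proposals
#' (see [modify_strength()]).
#'
#' @param genome A `genome_architecture`.
#' @param defaults Element defaults.
#' @return List with `genome` (the mutant), and `mutation` (a list with
#'   `action`, `kind`, `region`, `multiplier`, `n_draws`).
#' @export
propose_mutation <- function(genome, defaults = element_defaults()) {
  menu <- enumerate_mutations(genome)
  pick <- menu[sample.int(nrow(menu), 1), ]
  mutation <- list(action = pick$action, kind = pick$kind,
                   region = pick$region, multiplier = NA_real_,
                   n_draws = 0L)
  if (pick$action == "modify") {
    idx <- element_index(genome, pick$kind, pick$region)
    mod <- modify_strength(genome$elements$strength[idx],
                           defaults[[pick$kind]])
    mutation$multiplier <- mod$multiplier
    mutation$n_draws <- mod$n_draws
    mutant <- set_element_strength(genome, pick$kind, pick$region,
                                   mod$strength, defaults)
  } else {
    mutant <- apply_mutation(genome, mutation, defaults)
  }
  list(genome = mutant, mutation = mutation)
}

#' Origin-fixation acceptance probability
#'
#' Probability that a mutant with fitness `f_prime` replaces a resident
#' with fitness `f` in the accelerated origin-fixation model: beneficial or
#' neutral mutations (`f_prime >= f`) are accepted unconditionally;
#' deleterious ones with probability `(f_prime / f)^(2 * Ne)`, where `Ne`
#' is the simulated effective population size.
#'
#' For fitness functions that can be non-positive (linear decline), both
#' fitness values are shifted by `offset` before forming the ratio so the
#' power stays defined; `fermi` and `exponential` fitnesses are positive
#' and use `offset = 0`.
#'
#' @param f Resident fitness.
#' @param f_prime Mutant fitness.
#' @param Ne Effective population size (> 0; default 1000).
#' @param offset Non-negative shift applied to both fitnesses.
#' @return Probability in (0, 1].
#' @export
acceptance_probability <- function(f, f_prime, Ne = 1000, offset = 0) {
  if (Ne <= 0) stop("`Ne` must be positive")
  if (f_prime >= f) return(1)
  fr <- f + offset
  fpr <- f_prime + offset
  if (fr <= 0 || fpr <= 0)
    stop("fitness values must be positive after shifting; ",
         "set a larger `offset` for linear fitness")
  (fpr / fr)^(2 * Ne)
}

#' Simulated-annealing selection schedule
#'
#' Selection strength beta as a function of generation. For the canonical
#' 5000-generation run: beta = 1e-3 for the first 500 generations (broad,
#' nearly neutral exploration), then a linear increase to 1.1 by generation
#' 4500, then a linear increase to 1.3 by generation 5000 (freezing the
#' population onto one architecture). For other run lengths the phase
#' boundaries scale proportionally (10% / 80% / 10% of the total).
#'
#' @param generation Generation number(s), 1-based; values beyond `total`
#'   return `beta_end`.
#' @param total Total generations of the run (default 5000).
#' @param beta_start,beta_mid,beta_end Schedule endpoints (defaults 1e-3,
#'   1.1, 1.3).
#' @return Numeric vector of beta values, same length as `generation`.
#' @export
annealing_beta <- function(generation, total = 5000, beta_start = 1e-3,
                           beta_mid = 1.1, beta_end = 1.3) {
  p1 <- round(0.1 * total)
  p2 <- round(0.9 * total)
  g <- pmin(generation, total)
  ifelse(g <= p1, beta_start,
         ifelse(g <= p2,
                beta_start + (g - p1) / (p2 - p1) * (beta_mid - beta_start),
                beta_mid + (g - p2) / (total - p2) * (beta_end - beta_mid)))
}

#' Evolve a genome architecture toward a target expression pattern
#'
#' The origin-fixation generation loop: at each generation the annealing
#' schedule sets the selection strength beta; exactly one mutation is
#' proposed uniformly from the mutational neighbourhood of the resident;
#' the mutant is evaluated by replicate-averaged stochastic simulation and
#' its normalized RMSE to the target converted to fitness; the mutant then
#' replaces the resident with the origin-fixation acceptance probability.
#' One uniform acceptance draw is consumed every generation (even when
#' acceptance is certain) so trajectories are fully reproducible from the
#' master seed. The resident's cached distance is reused between
#' generations unless `reevaluate_resident = TRUE`.
#'
#' @param target Target `expression_time_course`; its gene set defines the
#'   genome size when `start` is not given.
#' @param start Starting `genome_architecture`; defaults to the
#'   single-promoter genome matching the target's gene count.
#' @param generations Number of generations (default 5000).
#' @param replicates Replicate simulations averaged per evaluation
#'   (default 10).
#' @param Ne Effective population size (default 1000).
#' @param fitness A [fitness_spec()]; its `beta` is overridden by the
#'   annealing schedule each generation.
#' @param sim_config A [simulation_config()]; its grid must match the
#'   target's.
#' @param defaults Element defaults.
#' @param seed Master seed; identical seeds give identical trajectories.
#' @param schedule Function mapping generation to beta; defaults to
#'   [annealing_beta()] scaled to `generations`.
#' @param reevaluate_resident Re-simulate the resident every generation
#'   instead of reusing its cached distance.
#' @return An object of class `evolution_state`: the final resident and its
#'   distance, the best-ever resident genome and distance, and a
#'   per-generation trajectory log (data frame with columns `generation`,
#'   `beta`, `action`, `kind`, `region`, `rmse_norm`, `fitness`,
#'   `accepted`, `resident_rmse`).
#' @export
evolve <- function(target, start = NULL, generations = 5000,
                   replicates = 10, Ne = 1000,
                   fitness = fitness_spec("fermi"),
                   sim_config = simulation_config(),
                   defaults = element_defaults(), seed = NULL,
                   schedule = NULL, reevaluate_resident = FALSE) {
  if (is.null(start)) {
    start <- make_starting_genome(length(tc_genes(target)), defaults)
    start$genes$name <- tc_genes(target)
  }
  if (!setequal(start$genes$name, tc_genes(target)))
    stop("gene names of `start` do not match the target's")
  if (is.null(schedule))
    schedule <- function(g) annealing_beta(g, total = generations)
  if (generations < 0) stop("`generations` must be >= 0")
  offset <- if (fitness$fun == "linear") fitness$offset else 0

  with_seed(seed, {
    evaluate <- function(genome) {
      s <- sample.int(.Machine$integer.max, 1)
      normalized_rmse(
        simulate_replicates(genome, sim_config, n = replicates, seed = s),
        target)
    }
    resident <- start
    resident_rmse <- evaluate(resident)
    best_genome <- resident
    best_rmse <- resident_rmse

    n <- generations
    traj <- data.frame(generation = seq_len(n),
                       beta = rep(NA_real_, n),
                       action = rep(NA_character_, n),
                       kind = rep(NA_character_, n),
                       region = rep(NA_integer_, n),
                       rmse_norm = rep(NA_real_, n),
                       fitness = rep(NA_real_, n),
                       accepted = rep(NA, n),
                       resident_rmse = rep(NA_real_, n))
    for (g in seq_len(n)) {
      beta <- schedule(g)
      spec_g <- fitness_spec(fitness$fun, beta, fitness$offset)
      if (reevaluate_resident) resident_rmse <- evaluate(resident)
      f <- fitness_of(resident_rmse, spec_g)
      prop <- propose_mutation(resident, defaults)
      mutant_rmse <- evaluate(prop$genome)
      f_prime <- fitness_of(mutant_rmse, spec_g)
      p_acc <- acceptance_probability(f, f_prime, Ne, offset)
      accepted <- stats::runif(1) < p_acc
      if (accepted) {
        resident <- prop$genome
        resident_rmse <- mutant_rmse
      }
      if (resident_rmse < best_rmse) {
        best_rmse <- resident_rmse
        best_genome <- resident
      }
      traj$beta[g] <- beta
      traj$action[g] <- prop$mutation$action
      traj$kind[g] <- prop$mutation$kind
      traj$region[g] <- prop$mutation$region
      traj$rmse_norm[g] <- mutant_rmse
      traj$fitness[g] <- f_prime
      traj$accepted[g] <- accepted
      traj$resident_rmse[g] <- resident_rmse
    }

    structure(list(
      resident = resident, resident_rmse = resident_rmse,
      best_genome = best_genome, best_rmse = best_rmse,
      generation = generations, Ne = Ne, fitness = fitness,
      replicates = replicates, trajectory = traj, seed = seed
    ), class = "evolution_state")
  })
}

#' @export
print.evolution_state <- function(x, ...) {
  cat(sprintf("Evolution state after %d generations\n", x$generation))
  cat(sprintf("  resident rmse_norm: %.4f  (best-ever: %.4f)\n",
              x$resident_rmse, x$best_rmse))
  cat(sprintf("  accepted mutations: %d / %d\n",
              sum(x$trajectory$accepted), nrow(x$trajectory)))
  cat("  resident architecture: ", fingerprint(x$resident), "\n", sep = "")
  invisible(x)
}

#' Write an evolution trajectory log to CSV
#'
#' @param state An `evolution_state`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(state, path) {
  utils::write.csv(state$trajectory, path, row.names = FALSE)
  invisible(path)
}
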