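#' Simulation configuration
#'
#' Kinetic and bookkeeping parameters of the single-molecule expression
#' simulator. The defaults describe a phage infecting a host cell whose
#' polymerase pool it co-opts: 4 host RNA polymerases (35 nt footprint)
#' transcribing at 40 nt/s over the first 300 s of infection, transcript
#' abundances sampled every 5 s. Degradation initiates at original
#' (nascent) 5' ends at `k_deg_nascent` per second and at RNase-cleaved 5'
#' ends `deg_fold` (1000) times faster, the exonucleolytic front then
#' advancing 5'->3' at `deg_speed` nt/s.
#'
#' @param n_polymerases Host polymerase copy number (default 4).
#' @param pol_footprint Polymerase footprint in nt (default 35); no two
#'   polymerases ever approach closer than this, and a promoter is occluded
#'   while a polymerase sits within a footprint of it.
#' @param ribosome_footprint Ribosome footprint in nt (default 30); kept
#'   for completeness, unused unless `translation = TRUE`.
#' @param pol_speed Transcription elongation speed, nt/s (default 40).
#' @param horizon Simulated real time in seconds (default 300).
#' @param sample_interval Sampling grid spacing in seconds (default 5);
#'   must divide `horizon`.
#' @param binding_scale Bimolecular binding constant: a free polymerase
#'   binds an unoccluded promoter with propensity
#'   `strength * free_polymerases * binding_scale` (default 2.5e-8 per
#'   strength unit per molecule per second).
#' @param k_deg_nascent Degradation-initiation rate at a nascent 5' end,
#'   per second (default 1e-5).
#' @param deg_fold Ratio of cleaved-end to nascent-end degradation
#'   initiation rates (default 1000).
#' @param deg_speed Exonuclease progression speed, nt/s (default 20).
#' @param seed Optional integer seed making the run reproducible.
#' @param translation Reserved hook; translation and protein dynamics are
#'   not modelled and only `FALSE` is accepted.
#' @param check_invariants Record engine self-checks (polymerase
#'   conservation, footprint exclusion) on every event.
#' @param log_events Return a per-run event log (binding, termination,
#'   cleavage, molecule creation with its degradation-initiation
#'   propensity).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_polymerases = 4, pol_footprint = 35,
                              ribosome_footprint = 30, pol_speed = 40,
                              horizon = 300, sample_interval = 5,
                              binding_scale = 2.5e-8, k_deg_nascent = 1e-5,
                              deg_fold = 1000, deg_speed = 20, seed = NULL,
                              translation = FALSE, check_invariants = FALSE,
                              log_events = FALSE) {
  cfg <- list(n_polymerases = as.integer(n_polymerases),
              pol_footprint = as.integer(pol_footprint),
              ribosome_footprint = as.integer(ribosome_footprint),
              pol_speed = pol_speed, horizon = horizon,
              sample_interval = sample_interval,
              binding_scale = binding_scale,
              k_deg_nascent = k_deg_nascent, deg_fold = deg_fold,
              deg_speed = deg_speed, seed = seed,
              translation = isTRUE(translation),
              check_invariants = isTRUE(check_invariants),
              log_events = isTRUE(log_events))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  rates <- c("pol_speed", "binding_scale", "k_deg_nascent", "deg_fold",
             "deg_speed")
  for (r in rates)
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0)
      stop("`", r, "` must be a non-negative number")
  if (cfg$n_polymerases < 1) stop("`n_polymerases` must be >= 1")
  if (cfg$horizon <= 0) stop("`horizon` must be positive")
  if (cfg$sample_interval <= 0 ||
      abs(cfg$horizon / cfg$sample_interval -
            round(cfg$horizon / cfg$sample_interval)) > 1e-9)
    stop("`sample_interval` must divide `horizon`")
  if (cfg$translation)
    stop("translation is not modelled; only mRNA dynamics are simulated")
  invisible(cfg)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

#' Simulate a gene-expression time course
#'
#' Runs the stochastic single-molecule simulator on a genome architecture.
#' Free polymerases bind unoccluded promoters, elongate one nucleotide at a
#' time, never approach within a footprint of a leading polymerase, and
#' either terminate at terminators (Bernoulli draw with probability equal
#' to the terminator strength, resolved once per passage) or read through.
#' Transcribed, intact RNase sites are cleaved with propensity equal to the
#' site strength; the downstream fragment acquires a cleaved 5' end, which
#' initiates degradation 1000-fold faster than a nascent end. A gene
#' contributes to the transcript count at a sample time only if its coding
#' sequence is fully transcribed and not yet reached by a degradation
#' front, whether the molecule is still nascent or released. The whole
#' genome is available for binding from time zero.
#'
#' @param genome A `genome_architecture`.
#' @param config A `simulation_config`.
#' @param seed Optional seed overriding `config$seed`.
#' @return An `expression_time_course`: data frame with column `time` and
#'   one count column per gene. Attributes `n_checks`/`n_violations` hold
#'   engine self-check tallies when `check_invariants = TRUE`, and `events`
#'   the event log when `log_events = TRUE`.
#' @export
simulate_expression <- function(genome, config = simulation_config(),
                                seed = NULL) {
  validate_genome(genome)
  validate_config(config)
  if (is.null(seed)) seed <- config$seed
  coords <- genome_coordinates(genome)
  el <- element_positions(genome)
  pick <- function(kind) el[el$kind == kind, , drop = FALSE]
  pr <- pick("promoter"); tr <- pick("terminator"); rs <- pick("rnase_site")

  res <- with_seed(seed, .sim_core(
    genome_length(genome), coords$genes$start, coords$genes$end,
    pr$position, pr$strength, tr$position, tr$strength,
    rs$position, rs$strength,
    config$n_polymerases, config$pol_footprint, config$pol_speed,
    config$horizon, config$sample_interval, config$binding_scale,
    config$k_deg_nascent, config$deg_fold, config$deg_speed,
    config$check_invariants, config$log_events
  ))

  counts <- res$counts
  colnames(counts) <- genome$genes$name
  tc <- time_course(res$times, counts)
  attr(tc, "n_checks") <- res$n_checks
  attr(tc, "n_violations") <- res$n_violations
  if (config$log_events) attr(tc, "events") <- decode_events(res$events)
  tc
}

event_names <- c("molecule_created_nascent", "molecule_created_cleaved",
                 "promoter_binding", "termination", "readthrough",
                 "cleavage", "runoff_release", "degradation_initiated")

decode_events <- function(ev) {
  data.frame(time = ev$time, event = event_names[ev$code],
             molecule = ev$molecule, value = ev$value,
             stringsAsFactors = FALSE)
}

#' Construct an expression time course
#'
#' A time course is a data frame with a `time` column (uniform grid from 0
#' to the horizon) and one non-negative numeric column per gene. Both
#' simulator output and target patterns use this container.
#'
#' @param times Numeric vector of sample times.
#' @param counts Matrix or data frame of per-gene values, one column per
#'   gene, one row per time.
#' @return An object of classes `expression_time_course` and `data.frame`.
#' @export
time_course <- function(times, counts) {
  counts <- as.data.frame(counts)
  if (nrow(counts) != length(times))
    stop("`counts` must have one row per time point")
  if (is.null(colnames(counts)) || any(colnames(counts) == ""))
    stop("`counts` columns must be named after genes")
  if (any(as.matrix(counts) < 0)) stop("counts must be non-negative")
  dt <- diff(times)
  if (length(dt) > 0 && any(abs(dt - dt[1]) > 1e-9))
    stop("time grid must be uniform")
  out <- cbind(data.frame(time = times), counts)
  rownames(out) <- NULL
  structure(out, class = c("expression_time_course", "data.frame"))
}

#' Gene names of a time course
#' @param tc An `expression_time_course`.
#' @return Character vector of gene column names.
#' @export
tc_genes <- function(tc) setdiff(names(tc), "time")

tc_matrix <- function(tc) as.matrix(tc[, tc_genes(tc), drop = FALSE])

#' Mean expression time course over independent replicates
#'
#' Runs `n` independent seeded simulations of the same genome and returns
#' the element-wise mean time course (counts may be fractional). Replicate
#' seeds are derived deterministically from the master seed, so the result
#' is reproducible.
#'
#' @param genome A `genome_architecture`.
#' @param config A `simulation_config`.
#' @param n Number of replicates (>= 1; default 10).
#' @param seed Master seed (overrides `config$seed`).
#' @return An `expression_time_course` of replicate means.
#' @export
simulate_replicates <- function(genome, config = simulation_config(),
                                n = 10, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("`n` must be a single integer >= 1")
  n <- as.integer(n)
  if (is.null(seed)) seed <- config$seed
  seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, n)
  } else {
    with_seed(seed, sample.int(.Machine$integer.max, n))
  }
  acc <- NULL
  for (i in seq_len(n)) {
    tc <- simulate_expression(genome, config, seed = seeds[i])
    m <- tc_matrix(tc)
    acc <- if (is.null(acc)) m else acc + m
    if (i == 1) times <- tc$time
  }
  time_course(times, acc / n)
}

#' Read and write time-course CSV files
#'
#' The CSV dialect used for both simulator output and target patterns:
#' header `time,<gene1>,<gene2>,...`, one row per sample time.
#'
#' @param path File path.
#' @param tc An `expression_time_course`.
#' @return `read_time_course()` returns an `expression_time_course`;
#'   `write_time_course()` returns `path` invisibly.
#' @export
read_time_course <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be `time`")
  time_course(df$time, df[, -1, drop = FALSE])
}

#' @rdname read_time_course
#' @export
write_time_course <- function(tc, path) {
  utils::write.csv(as.data.frame(tc), path, row.names = FALSE)
  invisible(path)
}
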