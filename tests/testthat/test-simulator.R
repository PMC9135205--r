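test_that("no promoter means no expression, certain termination blocks downstream genes", {
  bare <- genome_architecture(
    data.frame(name = c("g1", "g2", "g3"), length = 150))
  tc <- simulate_expression(bare, quick_cfg(), seed = 1)
  expect_true(all(tc[, tc_genes(tc)] == 0))

  blocked <- terminated_genome(1.0)
  tc <- simulate_expression(blocked, simulation_config(), seed = 1)
  expect_true(all(tc$gene2 == 0))
  expect_true(all(tc$gene3 == 0))
  expect_gt(max(tc$gene1), 0)
})

test_that("fixed seeds give bit-identical trajectories", {
  g <- positive_control_genome()
  cfg <- simulation_config(log_events = TRUE)
  a <- simulate_expression(g, cfg, seed = 42)
  b <- simulate_expression(g, cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "events"), attr(b, "events"))
  c <- simulate_expression(g, cfg, seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("engine self-checks find no footprint overlap or polymerase leak", {
  # dense traffic: strong promoters feeding the same genes
  g <- positive_control_genome()
  g <- set_element_strength(g, "promoter", 0L, 1e9)
  g <- set_element_strength(g, "promoter", 1L, 1e9)
  cfg <- simulation_config(check_invariants = TRUE)
  for (seed in 1:5) {
    tc <- simulate_expression(g, cfg, seed = seed)
    expect_gt(attr(tc, "n_checks"), 0)
    expect_equal(attr(tc, "n_violations"), 0)
  }
})

test_that("counts are non-decreasing when cleavage and degradation are off", {
  g <- make_starting_genome(3)
  g <- add_element(g, "terminator", 1L, 0.5)  # termination alone cannot
  cfg <- simulation_config(k_deg_nascent = 0)  # remove a finished transcript
  for (seed in 1:5) {
    tc <- simulate_expression(g, cfg, seed = seed)
    for (gene in tc_genes(tc))
      expect_true(all(diff(tc[[gene]]) >= 0))
  }
})

test_that("mean abundance matches the delayed-birth-process expectation", {
  # A single weak promoter (rare initiation, negligible polymerase queueing),
  # no terminators/cleavage/degradation: completed transcripts accumulate as
  # a Poisson counting process delayed by the elongation time from the
  # promoter to the gene's 3' end. Expected count at the horizon is
  # lambda * (T - d), lambda = strength * n_pol * binding_scale,
  # d = (gene_end - promoter_position) / pol_speed.
  g <- genome_architecture(
    data.frame(name = "g1", length = 30),
    data.frame(kind = "promoter", region = 0L, strength = 1e5))
  cfg <- simulation_config(k_deg_nascent = 0)
  lambda <- 1e5 * cfg$n_polymerases * cfg$binding_scale
  ep <- phagevolve:::element_positions(g)
  d <- (genome_coordinates(g)$genes$end - ep$position) / cfg$pol_speed
  expected <- lambda * (cfg$horizon - d)

  n <- 400
  tc <- simulate_replicates(g, cfg, n = n, seed = 7)
  observed <- tc$g1[nrow(tc)]
  se <- sqrt(expected / n)  # Poisson variance
  expect_lt(abs(observed - expected), 4 * se)
})

test_that("variance of the replicate mean shrinks like 1/n", {
  g <- make_starting_genome(2)
  cfg <- quick_cfg()
  set.seed(11)
  var_of_mean <- function(n_rep) {
    finals <- replicate(24, mean_final_count(g, cfg, "gene1", n_rep,
                                             seed = sample.int(1e8, 1)))
    stats::var(finals)
  }
  v <- vapply(c(4, 16, 64), var_of_mean, 0)
  expect_gt(v[1], v[2])
  expect_gt(v[2], v[3])
  expect_gt(v[1] / v[3], 4)   # expected 16, generous stochastic band
  expect_lt(v[1] / v[3], 80)
})

test_that("gene-2 abundance responds monotonically to terminator strength", {
  cfg <- simulation_config()
  means <- vapply(c(0, 0.3, 0.7, 1), function(s) {
    g <- if (s > 0) terminated_genome(s) else make_starting_genome(3)
    mean_final_count(g, cfg, "gene2", n = 100, seed = 101)
  }, 0)
  expect_true(all(diff(means) < 0))
  expect_equal(means[4], 0)
})

test_that("cleavage produces a plateau while its absence keeps counts growing", {
  cfg <- simulation_config()
  with_site <- add_element(make_starting_genome(2), "rnase_site", 0L, 0.05)
  without <- make_starting_genome(2)
  late_slope <- function(genome) {
    tc <- simulate_replicates(genome, cfg, n = 100, seed = 5)
    late <- tc$time >= 200
    stats::coef(stats::lm(tc$gene1[late] ~ tc$time[late]))[2]
  }
  growth <- late_slope(without)
  plateau <- late_slope(with_site)
  expect_gt(growth, 0.03)             # keeps accumulating transcripts
  expect_lt(abs(plateau), growth / 4) # steady state: late slope near zero
})

test_that("replicate means are deterministic and n = 1 equals a single run", {
  g <- positive_control_genome()
  cfg <- quick_cfg()
  a <- simulate_replicates(g, cfg, n = 10, seed = 3)
  b <- simulate_replicates(g, cfg, n = 10, seed = 3)
  expect_identical(as.data.frame(a), as.data.frame(b))

  one <- simulate_replicates(g, cfg, n = 1, seed = 3)
  seed1 <- phagevolve:::with_seed(3, sample.int(.Machine$integer.max, 1))
  single <- simulate_expression(g, cfg, seed = seed1)
  expect_equal(as.matrix(one[, tc_genes(one)]),
               as.matrix(single[, tc_genes(single)]),
               ignore_attr = TRUE)
  expect_error(simulate_replicates(g, cfg, n = 0), "n")
})

test_that("time-course CSV files round-trip", {
  g <- positive_control_genome()
  tc <- simulate_expression(g, quick_cfg(), seed = 2)
  path <- temp_path(".csv")
  write_time_course(tc, path)
  back <- read_time_course(path)
  expect_equal(back$time, tc$time)
  expect_equal(as.matrix(back[, tc_genes(back)]),
               as.matrix(tc[, tc_genes(tc)]), ignore_attr = TRUE)
  unlink(path)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(simulation_config(horizon = 300, sample_interval = 7),
               "divide")
  expect_error(simulation_config(pol_speed = -1), "non-negative")
  expect_error(simulation_config(n_polymerases = 0), "n_polymerases")
  expect_error(simulation_config(translation = TRUE), "translation")
})
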