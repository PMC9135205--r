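test_that("mutation enumeration covers adds, removes and modifies exactly", {
  start <- make_starting_genome(3)  # 12 slots, 1 promoter present
  menu <- enumerate_mutations(start)
  expect_equal(nrow(menu), 13)
  expect_equal(sum(menu$action == "add"), 11)
  expect_equal(sum(menu$action == "remove"), 1)
  expect_equal(sum(menu$action == "modify"), 1)

  saturated <- start
  for (r in 0:3) for (k in element_kinds()) {
    if (!(k == "promoter" && r == 0))
      saturated <- add_element(saturated, k, r)
  }
  menu <- enumerate_mutations(saturated)
  expect_equal(sum(menu$action == "add"), 0)
  expect_equal(sum(menu$action == "remove"), 12)
  expect_equal(sum(menu$action == "modify"), 12)

  bare <- genome_architecture(data.frame(name = "g1", length = 150))
  menu <- enumerate_mutations(bare)
  expect_true(all(menu$action == "add"))
  expect_equal(nrow(menu), 6)  # 2 regions x 3 kinds
})

test_that("strength modification multiplies by Normal(1, 0.1) and redraws out-of-bounds", {
  b <- list(min = 0, max = 1)
  set.seed(1)
  res <- modify_strength(0.2, b)
  expect_equal(res$strength, 0.2 * res$multiplier)
  expect_true(res$strength >= 0 && res$strength <= 1)

  # near the upper bound redraws must occur and the result stays in bounds
  set.seed(2)
  redraws <- replicate(500, modify_strength(0.999, b)$n_draws)
  expect_true(any(redraws > 1))
  set.seed(3)
  vals <- replicate(500, modify_strength(0.999, b)$strength)
  expect_true(all(vals <= 1 & vals >= 0))

  # far from the bounds the accepted multipliers are the raw normal draws
  set.seed(4)
  mult <- replicate(2000, modify_strength(0.5, b)$multiplier)
  expect_lt(abs(mean(mult) - 1), 3 * 0.1 / sqrt(2000))
  expect_lt(abs(sd(mult) - 0.1), 0.01)

  # deterministic multiplier arithmetic
  g <- terminated_genome(0.2)
  m <- list(action = "modify", kind = "terminator", region = 1L,
            multiplier = 1.1)
  expect_equal(apply_mutation(g, m)$elements$strength[
    g$elements$kind == "terminator"], 0.22)
})

test_that("origin-fixation acceptance follows the fitness-ratio power law", {
  expect_equal(acceptance_probability(0.5, 0.5, 1000), 1)
  expect_equal(acceptance_probability(0.3, 0.4, 1000), 1)
  expect_equal(acceptance_probability(0.5, 0.4999, 1000),
               (0.4999 / 0.5)^2000)
  expect_equal(round(acceptance_probability(0.5, 0.4999, 1000), 4), 0.6703)

  # monotone increasing in mutant fitness, always in (0, 1]
  p <- vapply(seq(0.40, 0.50, by = 0.01),
              function(fp) acceptance_probability(0.5, fp, 1000), 0)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p <= 1))

  # linear fitness values are non-positive; the offset keeps the ratio defined
  expect_error(acceptance_probability(-0.2, -0.3, 10), "positive")
  p <- acceptance_probability(-0.2, -0.3, 10, offset = 1)
  expect_equal(p, (0.7 / 0.8)^20)
})

test_that("annealing schedule hits its endpoints and scales proportionally", {
  expect_equal(annealing_beta(1), 1e-3)
  expect_equal(annealing_beta(500), 1e-3)
  expect_equal(annealing_beta(4500), 1.1)
  expect_equal(annealing_beta(5000), 1.3)
  b <- annealing_beta(1:5000)
  expect_true(all(diff(b) >= 0))
  # continuity at the phase boundaries
  expect_lt(annealing_beta(501) - annealing_beta(500), 1e-3)
  expect_lt(annealing_beta(4501) - annealing_beta(4500), 1e-3)

  # 10% / 80% / 10% split for other run lengths
  expect_equal(annealing_beta(100, total = 1000), 1e-3)
  expect_equal(annealing_beta(900, total = 1000), 1.1)
  expect_equal(annealing_beta(1000, total = 1000), 1.3)
})

test_that("proposals are uniform over the enumerated mutation set", {
  g <- positive_control_genome()  # frozen genome: 7 adds, 5 removes, 5 modifies
  menu <- enumerate_mutations(g)
  n <- 10000
  set.seed(21)
  keys <- replicate(n, {
    m <- propose_mutation(g)$mutation
    paste(m$action, m$kind, m$region)
  })
  observed <- table(factor(keys, levels = paste(menu$action, menu$kind,
                                                menu$region)))
  expect_equal(sum(observed), n)
  chisq <- stats::chisq.test(observed)
  expect_gt(chisq$p.value, 0.001)
})

test_that("evolution trajectories are reproducible and track the best resident", {
  tgt <- make_positive_control(positive_control_genome(), quick_cfg(),
                               n_replicates = 2, seed = 5)
  run <- function() evolve(tgt, generations = 25, replicates = 2,
                           sim_config = quick_cfg(), seed = 17)
  a <- run()
  b <- run()
  expect_identical(a$trajectory, b$trajectory)
  expect_equal(a$resident, b$resident)

  expect_equal(nrow(a$trajectory), 25)
  expect_true(all(a$trajectory$action %in% c("add", "remove", "modify")))
  # best-ever statistic equals the running minimum of resident distances
  expect_equal(a$best_rmse, min(a$trajectory$resident_rmse))
  expect_true(all(cummin(a$trajectory$resident_rmse) >=
                    a$best_rmse - 1e-12))

  # zero-generation run: state is well-formed, start genome evaluated
  z <- evolve(tgt, generations = 0, replicates = 2,
              sim_config = quick_cfg(), seed = 17)
  expect_equal(nrow(z$trajectory), 0)
  expect_gte(z$resident_rmse, 0)
  expect_equal(fingerprint(z$resident),
               fingerprint(make_starting_genome(3)))
})

test_that("with beta = 0 all fitnesses are equal and every proposal is accepted", {
  tgt <- make_positive_control(positive_control_genome(), quick_cfg(),
                               n_replicates = 1, seed = 6)
  st <- evolve(tgt, generations = 30, replicates = 1,
               sim_config = quick_cfg(), seed = 8,
               schedule = function(g) 0)
  expect_true(all(st$trajectory$accepted))
  expect_true(all(st$trajectory$fitness == 0.5))  # Fermi at beta = 0
})
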