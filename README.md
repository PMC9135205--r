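# phagevolve

Designing a small phage genome that expresses its genes in a prescribed,
time-varying way usually means building a regulatory circuit — extra genes
whose only job is to control other genes. `phagevolve` explores the
alternative: it evolves, entirely in silico, the *placement and strengths*
of three basic regulatory elements — promoters, transcriptional
terminators, and RNase cleavage sites — on a small linear genome until the
simulated transcript time courses match a user-supplied target pattern. No
regulatory proteins, no circuitry: expression dynamics arise from the
balance of transcription, termination, cleavage and degradation alone.

The package is aimed at synthetic biologists and computational biologists
studying phage genome organisation, and at anyone who wants a compact,
fully reproducible test bed for evolutionary genome design.

## What it computes

**Simulator.** A stochastic, single-molecule discrete-event simulation of
the first minutes of infection: a fixed pool of host RNA polymerases (4 by
default, 35 nt footprint) binds unoccluded promoters with propensity
`strength × free polymerases × binding constant`, elongates at 40 nt/s
without ever overlapping another polymerase, terminates at terminators with
probability equal to the terminator strength (else reads through), and
transcribed RNase sites are cleaved with propensity equal to the site
strength. Degradation initiates at 5′ ends — 1000-fold faster at
RNase-cleaved ends than at original nascent ends — and chews 5′→3′ at
20 nt/s. A gene counts toward the transcript abundance `y_k(t)` only while
its coding sequence is fully transcribed and intact.

**Distance and fitness.** Simulated and target patterns are compared by a
normalized RMSE,

    RMSE_k     = sqrt( Σ_t [y_k(t) − Y_k(t)]² / T )
    RMSE_norm  = Σ_k RMSE_k / (M · Ȳ_k),    Ȳ_k = Σ_t Y_k(t) / T

summed over the M genes; `RMSE_norm ≤ 0.1` defines a successful match.
Fitness is the Fermi function `f = 1 / (exp(β · RMSE_norm) + 1)`
(exponential and linear declines are also available), with selection
strength β driven by a simulated-annealing schedule
(β = 10⁻³ for the first 10% of generations, linear to 1.1 by 90%, linear to
1.3 at the end).

**Evolution.** An accelerated origin–fixation model: each generation one
mutation (add / remove / retune an element) is drawn uniformly from the
exhaustive mutation set of the resident genome, the mutant is evaluated by
replicate-averaged simulation, and it fixes with probability 1 if
beneficial, else `(f′/f)^(2·Ne)` with `Ne = 1000`.

Around the core, the package provides gene-arrangement search over all
permutations of the target's genes, greedy pruning of regulatory elements
whose removal keeps the genome successful, and Shannon-entropy diversity
analysis of the evolved architecture fingerprints.

## Worked example

Evolve a three-gene genome toward a positive-control target — a pattern
generated by a known architecture, so an exact solution exists:

```r
library(phagevolve)

cfg    <- simulation_config()            # 300 s horizon, 4 polymerases
known  <- positive_control_genome()      # promoters r0/r1, rnase r1, terminators r2/r3
target <- make_positive_control(known, cfg, n_replicates = 3, seed = 1)

state <- evolve(target, generations = 1000, replicates = 3,
                sim_config = cfg, seed = 1)
state
#> Evolution state after 1000 generations
#>   resident rmse_norm: 0.0619  (best-ever: 0.0619)
#>   accepted mutations: 124 / 1000
#>   resident architecture: terminator@0|promoter@0|terminator@1|promoter@1|rnase_site@1|terminator@2
is_successful(state$best_rmse)
#> [1] TRUE
```

The evolved genome reaches a normalized RMSE of 0.0619 — below the 0.1
success threshold — with an architecture *similar but not identical* to the
one that generated the target (it re-discovers the promoter pair and the
cleavage site before gene 2, plus a spurious co-located terminator pair).

Elements whose strengths evolved toward zero can be pruned away:

```r
clean     <- set_element_strength(make_starting_genome(2), "promoter", 0, 1e8)
target2   <- make_positive_control(clean, cfg, n_replicates = 5, seed = 1)
cluttered <- add_element(clean, "terminator", 1, 1e-6)
res <- prune_genome(cluttered, target2, cfg, replicates = 3, seed = 2)
res$log
#>   step       kind region strength  rmse_after
#> 1    1 terminator      1    1e-06 0.008853733
```

The do-nothing terminator is removed; the pruned genome still matches the
target (rmse 0.0089). Diversity of a set of evolved solutions is summarised
as entropy over architecture fingerprints: 50 solutions split evenly
between two architectures give `architecture_entropy(...) = 1` bit.

A command-line interface (`inst/scripts/phagevolve`) wraps the same
functions as `simulate`, `evolve`, `prune`, `entropy`, `arrange` and
`make-target` subcommands; every run writes a manifest JSON beside its
outputs.

## Further reading

The methods vignette (`vignettes/phagevolve-methods.Rmd`) documents the
simulation model and its assumptions, every tunable parameter with units
and defaults, the annealing and acceptance machinery, what the built-in
target generators do and do not emulate, and known limitations.
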