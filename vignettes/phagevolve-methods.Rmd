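---
title: "Evolving phage genome architectures: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving phage genome architectures: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phagevolve` evolves the placement and strengths of promoters, terminators
and RNase cleavage sites on a small linear genome so that stochastically
simulated transcript time courses match a target expression pattern. This
vignette documents the model, its parameters, and the design decisions
behind the implementation.

## The genome model

A genotype is a *genome architecture*: M protein-coding genes (150 nt each
by default) laid out 5′→3′ on a single strand, separated by M + 1
regulatory regions (50 nt spacers): region 0 upstream of gene 1, region i
between genes i and i + 1, region M downstream of the last gene. Each
region can hold at most one element of each kind. Elements are point
features at fixed fractional offsets inside their spacer, in the 5′→3′
order **terminator → promoter → rnase_site**. This order is load-bearing:
a terminator ends transcripts arriving from upstream *before* they reach
the co-located promoter, and a cleavage site placed with a promoter in the
same region falls *inside* transcripts initiated at that promoter — the
motif that decouples the expression of adjacent genes. Promoters or
cleavage sites in the final region are legal but inert (no gene lies
downstream); the evolutionary engine may still propose them.

Element strengths live in kind-specific bounds, with insertion defaults
used whenever an element is added:

| kind        | meaning                      | insert  | bounds        |
|-------------|------------------------------|---------|---------------|
| promoter    | binding-rate constant        | 10^6    | [10^5, 10^13] |
| terminator  | termination probability      | 0.2     | [0, 1]        |
| rnase_site  | cleavage-rate constant (1/s) | 5×10^-3 | [0, 1]        |

Coordinates are 1-based and inclusive throughout; there is no nucleotide
sequence, no reverse strand, and genes never overlap.

## The expression simulator

Expression is simulated at single-molecule resolution with a Gillespie
direct-method engine (implemented in C++ for speed; all randomness flows
through R's RNG so runs are bit-reproducible under a seed):

* **Binding.** A free polymerase binds an unoccluded promoter with
  propensity `strength × free_count × binding_scale`. A promoter is
  occluded while any polymerase sits within one footprint of it.
* **Elongation.** Each bound polymerase steps 1 nt with rate `pol_speed`
  and is blocked whenever the step would bring it within `pol_footprint`
  nucleotides of the polymerase ahead (molecular collision/exclusion).
* **Termination.** Landing on a terminator resolves a single Bernoulli
  draw: terminate with probability equal to the strength, else read
  through. Termination is per-passage, not rate-based, so each polymerase
  is tested exactly once per terminator.
* **Cleavage.** Every fully transcribed, still-intact cleavage site on any
  molecule (nascent or released) is an exponential channel with propensity
  equal to the site strength. Cleavage splits the molecule; the downstream
  fragment keeps the polymerase (if any) and acquires a *cleaved* 5′ end;
  the cut destroys the site on the upstream fragment.
* **Degradation.** A molecule's 5′ end initiates degradation at
  `k_deg_nascent` (original ends) or `deg_fold × k_deg_nascent` (cleaved
  ends); the front then consumes nucleotides 5′→3′ at `deg_speed`. A gene
  leaves the molecule's intact set the moment its first nucleotide is
  consumed.
* **Counting.** At each sample time, gene k's abundance is the number of
  molecules whose copy of gene k is fully transcribed and intact —
  partially transcribed genes never count, fully transcribed genes on
  still-nascent molecules do.

The whole genome is available for binding from t = 0 (no entry dynamics).
Translation is deliberately not modelled; only mRNA dynamics matter here,
and the `translation` configuration flag exists solely to make that
explicit.

### Parameters, units, defaults

| parameter        | unit                  | default | rationale |
|------------------|-----------------------|---------|-----------|
| n_polymerases    | molecules             | 4       | small host pool co-opted by the phage; keeps runs fast |
| pol_footprint    | nt                    | 35      | realistic polymerase footprint; enforces exclusion |
| ribosome_footprint | nt                  | 30      | reserved for the (disabled) translation hook |
| pol_speed        | nt/s                  | 40      | bacterial elongation-rate scale |
| horizon          | s                     | 300     | first five minutes of infection |
| sample_interval  | s                     | 5       | 61-point grid; targets must share it |
| binding_scale    | 1/(strength·molecule·s) | 2.5e-8 | calibrated so the 10^6 default promoter initiates ≈0.1/s |
| k_deg_nascent    | 1/s                   | 1e-5    | nascent ends are nearly stable on a 300 s horizon |
| deg_fold         | —                     | 1000    | cleaved ends degrade 1000-fold faster |
| deg_speed        | nt/s                  | 20      | exonuclease slower than polymerase |

The kinetic constants the simulator needs but the genome model does not fix
(`binding_scale`, `pol_speed`, `k_deg_nascent`, `deg_speed`,
`sample_interval`) are this package's own calibration, chosen once so that
a default promoter yields tens of transcripts per gene over 300 s — the
regime in which termination, cleavage and degradation all visibly shape the
time course. They are configuration, not biology: all appear in
`simulation_config()` with documented units.

With these defaults the characteristic behaviours are: promoter+terminator
combinations produce linear accumulation at kind-specific rates (element
effects are independent of current abundance); RNase sites produce
plateaus, because degradation after cleavage is proportional to transcript
abundance and eventually balances production; a weak site after a strong
promoter merely attenuates accumulation on this horizon — the steady state
exists but lies beyond 300 s.

## Targets

Targets are time courses on the simulation grid with strictly positive
per-gene means (required by the normalization below). Three generators are
provided:

* `make_linear_pattern()` — `Y_k(t) = slope_k · t`;
* `make_plateau_pattern()` — ramp-then-plateau per gene; cross-over
  patterns arise from per-gene (slope, breakpoint) choices;
* `make_positive_control()` — the replicate-mean simulation of a known
  architecture, re-labelled as target. Because the generating genome
  exists, an exact solution is guaranteed; this is the canonical check that
  the evolutionary engine works.

`target_presets()` ships ten named (slope, breakpoint) parameter sets
spanning the qualitative classes — equal/distinct linear ramps, plateaus at
distinct levels, staggered plateaus, single/double/late cross-overs. They
are explicitly *approximate*, parametric stand-ins for those pattern
classes, not reconstructions of any specific published targets.
Oscillatory or decreasing targets are out of scope: nothing in this
regulatory vocabulary can lower an absolute transcript count on demand.

## Distance, fitness, evolution

The distance between observed pattern y and target Y is

```
RMSE_k    = sqrt( Σ_t [y_k(t) − Y_k(t)]² / T )
RMSE_norm = Σ_k RMSE_k / (M · Ȳ_k)
```

with `Ȳ_k` the gene's mean target abundance and T the number of grid
points (the t = 0 row is included; it contributes nothing to RMSE_k for
targets that start at zero but does enter Ȳ_k). The per-gene
normalization is applied *inside* the sum, exactly as written — each gene's
error is measured relative to its own abundance scale, so low- and
high-expressed genes count equally. The statistic is invariant under joint
positive rescaling of y and Y. `RMSE_norm ≤ 0.1` (inclusive) defines
success.

Fitness is, by default, the Fermi function `f = 1/(exp(β·r) + 1)`, which is
1/2 at r = 0 and declines smoothly; exponential (`exp(−β·r)`) and linear
(`−β·r`) declines are available. Because linear fitness is non-positive,
the origin–fixation ratio is formed after shifting both values by a
configurable positive offset (default 1) — an implementation decision the
fitness ratio model itself does not dictate, exposed in `fitness_spec()`.

Each generation: β comes from the annealing schedule; exactly one mutation
is proposed, uniformly over the exhaustive mutation set (one `add` per
empty kind×region slot, one `remove` and one `modify` per existing
element); strength modifications multiply by a Normal(1, 0.1) draw,
redrawing *only the multiplier* until the product is in bounds; the mutant
is evaluated by replicate-averaged simulation; and it replaces the resident
with probability 1 if `f′ ≥ f`, else `(f′/f)^(2·Ne)` with Ne = 1000. One
uniform acceptance draw is consumed every generation even when acceptance
is certain, keeping trajectories reproducible position-by-position from the
master seed. The resident's cached distance is reused between generations
(`reevaluate_resident = TRUE` re-simulates it each generation at double the
cost; with the annealing schedule we saw no benefit).

The annealing schedule is piecewise linear in the generation count: β =
10⁻³ for the first 10% of generations (nearly neutral exploration of
architectures), rising linearly to 1.1 at 90%, then to 1.3 at 100%
(freezing onto one architecture). For the canonical 5000-generation run the
phase boundaries are generations 500 and 4500; other run lengths scale the
10/80/10 split proportionally.

Both the final resident and the best-ever resident (the accepted genotype
with the lowest evaluated distance) are returned; reported results use the
best-ever value, which is also what the success threshold is applied to.

## Evaluation noise and what success means

Evaluations are stochastic: with 3 replicates per evaluation, the
positive-control genome's own distance to a 3-replicate target fluctuates
around ≈0.15–0.2 under the default abundance scale (tens of transcripts per
gene). Two consequences are worth knowing:

* The best-ever distance is a minimum over ~10³ noisy evaluations and is
  therefore optimistically biased (winner's curse). A genome whose
  best-ever evaluation was below 0.1 can re-evaluate above it on a fresh
  seed. This mirrors any stochastic-evaluation pipeline; raising the
  replicate count tightens the evaluations at linear cost.
* `prune_genome()` applies the threshold to fresh replicate-mean
  evaluations, so pruning directly after evolution can legitimately refuse
  a genome whose best-ever value squeaked under the threshold. Pruning is
  most meaningful in lower-noise regimes (stronger promoters, more
  replicates).

## Arrangements, pruning, diversity

**Arrangements.** Transcription is directional, so which *target* gene each
*genome* gene must match matters. `arrangement_search()` evolves every
permutation of the target's columns (3! = 6 for three genes) and ranks
arrangements by mean final distance, ties broken by enumeration order.
Exhaustive search beyond 5 genes is refused unless forced.

**Pruning.** Strengths can evolve to values so small the element is inert.
Greedy ablation removes, at each step, the candidate element whose removal
leaves the lowest replicate-mean distance, provided that distance stays at
or below the threshold, and stops at the first fixed point. "Least impact"
is interpreted as *smallest post-removal distance* (the alternative,
smallest change in distance, is available via `criterion = "delta"`). Ties
break by (region, kind) order. The procedure deliberately ignores epistasis
between elements.

**Diversity.** Evolved solutions are reduced to fingerprints — the sorted
(kind, region) presence/absence pairs, strengths ignored — and the set of
successful, pruned solutions is summarised by Shannon entropy
`H = −Σ (n_i/n) log₂(n_i/n)` in bits: 0 when one architecture dominates,
log₂(u) for u equally frequent architectures.

## Numerical and degenerate-input choices

* Element point positions are at 30% / 50% / 80% of the spacer
  (terminator / promoter / rnase_site), preserving the within-region order
  for any spacer ≥ 5 nt; elements consume no sequence.
* A polymerase binds with its active site at the promoter position;
  binding requires no other polymerase within one footprint on either
  side.
* A degradation front on a nascent molecule stalls when it catches the
  polymerase and resumes as the transcript grows.
* Zero-promoter genomes simulate to all-zero counts; they are rejected as
  *targets* (zero mean abundance breaks the normalization) but are legal
  simulation inputs.
* `generations = 0` returns a well-formed state containing only the
  evaluated start genome.
* Replicate seeds are drawn from the master seed via R's RNG; all `seed`
  arguments accept `NULL` (use the ambient RNG stream) and never disturb
  the caller's stream otherwise.

## Problem sizes used by the test suite

The package's own test and acceptance runs use desk-scale sizes chosen to
exercise every code path with tight statistics: 1000-generation evolutions
with 3 replicates per evaluation for the positive control (the canonical
run length is 5000 generations with 10 replicates), 100–400 replicate
batches for simulator distribution checks, 10⁴ proposals for the
uniformity test, and 10⁵ draws for the modification-multiplier mean. The
positive-control criterion is stochastic by construction; it is evaluated
as the minimum best-ever distance across three seeded runs.

## Limitations

* mRNA only: no translation, ribosome traffic, or protein read-out.
* A fixed host polymerase pool; phage-encoded polymerases and host
  resource competition beyond that pool are not modelled.
* No gene-order mutations (arrangement search permutes the *target*
  labels, not the genome), no overlapping genes, no nucleotide sequences.
* Element strengths are composite rate constants; mapping them onto real
  parts libraries is a calibration exercise outside this package's scope.
* Greedy pruning can miss minimal architectures reachable only through
  compensatory double removals.
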