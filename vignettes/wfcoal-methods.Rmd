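---
title: "Genealogy models, statistics and design choices in wfcoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genealogy models, statistics and design choices in wfcoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wfcoal)
```

## The problem

Coalescent simulators are the workhorse for generating genome-scale genetic
variation, but Hudson's model was derived for short regions and small
samples. Over a whole genome its recombination mechanism misbehaves: every
recombination event creates a brand-new, independent ancestral lineage, so a
sample can accumulate far more simulated ancestors than the population
contains — a haploid genome that in reality has exactly one diploid parent
is spread over many fictitious ones. The distortion inflates the number of
surviving lineages above the haploid population size `2N`, erases the
long-range correlations that relatives and admixture induce across
chromosomes, and biases identity-by-descent (IBD), long-range linkage
disequilibrium (LD) and ancestry-variance patterns exactly where large
cohorts carry their signal.

`wfcoal` implements, in one framework with a shared genealogy
representation:

* **Hudson's coalescent with recombination** (`model = "hudson"`):
  exponential waiting times, recombination at a rate equal to the total map
  length spanned by ancestral material (including "trapped" non-ancestral
  gaps), common-ancestor events at rate `k(k-1)/(4N(t))` per population.
* **A backwards discrete-time Wright-Fisher model** (`model = "dtwf"`):
  generations are iterated one at a time; each lineage draws a single
  uniform diploid parent; one meiosis — Poisson(`span in Morgans`)
  crossovers, a fair phase coin, an independent-assortment coin per
  chromosome boundary — splits its material between the parent's two
  haplotypes; everything landing on the same parental haplotype coalesces,
  possibly many lineages at once. Each gamete therefore has exactly one
  diploid parent and the lineage count can never exceed `2N(t)`.
* **A hybrid** (`model = "hybrid"`): DTWF for the recent `switch_time`
  generations, Hudson beyond, handing over the extant lineages and the
  genome-wide coalescence bookkeeping seamlessly. `switch_time = 0`
  reproduces pure Hudson and `switch_time = Inf` pure DTWF exactly
  (same seed, same tables).

Both engines record the genealogy as node and edge tables (times in
generations, half-open genomic intervals in Morgans) and prune genomic
intervals as soon as every sample has found its most recent common ancestor
there.

## Coordinates, maps and the inter-chromosome spacer

All coordinates are genetic (Morgans) on a single concatenated axis;
physical positions are produced only on output, through a uniform
`bp_per_morgan` scale (default 1 cM/Mb). A `genetic_map()` lays chromosomes
end-to-end with an optional `spacer` between them:

* Hudson's linear-rate model cannot represent independent assortment, so the
  spacer is ordinary recombining distance — a configurable approximation
  (default 0.5 Morgans) whose effect can be studied directly.
* The DTWF meiosis never places crossovers inside spacers; it flips an
  independent fair coin at every chromosome boundary. DTWF results are
  therefore invariant to the spacer value (a property the test suite
  asserts).

One consequence matters for experiment design: one generation back, a
0.5-Morgan spacer leaves adjacent chromosomes `exp(-0.5) = 61%` correlated
under Hudson, whereas truly unlinked chromosomes co-segregate with
probability 1/2 per meiosis and — under the coalescent — have *independent*
genealogies. For analyses of cross-chromosome correlation (ancestry
variance, unlinked-loci LD) the package therefore uses a 10-Morgan spacer,
which makes the Hudson engine's chromosomes effectively independent while
leaving the DTWF arm untouched. With the 0.5-Morgan default the
DTWF/Hudson ancestry-variance ratio reads ~12 instead of ~18 purely because
of the concatenation artifact.

The bundled `human22_map()` is a human-like fixture: 22 autosomes with
realistic sex-averaged genetic lengths totalling ≈36 Morgans, shipped as a
TSV. No expectation in the package hard-codes its values; everything is
computed from the map object.

## Demography, pulses and census nodes

Populations follow the backward size convention `N(t) = N0 exp(-alpha t)`
(continuous for Hudson, rounded with a floor of one diploid for DTWF).
Migration is parameterised backwards: `m[i, j]` is the per-generation
probability that a lineage in `i` draws its parent from `j`; Hudson uses
the same numbers as continuous rates. The DTWF within-generation order is
fixed: demographic events, then migration, then parent choice and meiosis,
then coalescence.

A pulse of admixture at generation `g` routes each lineage of the
destination population to the source with probability `f` — the paper-level
semantics that migration moves *haploid lineages*. Timing is post-meiosis:
the pulse acts on the generation-`g` lineages, i.e. the ancestors `g`
meioses above the samples. The engine then splices a census node onto every
extant lineage (at time `g + 0.5` under DTWF, between the integer
generations; at `g` exactly under Hudson), so each sample's genome can be
partitioned by which census ancestor — migrant or resident — carries it.
Because fully-coalesced intervals are normally pruned, census runs retain
them (`keep_coalesced = TRUE`, arranged by `admixture_config()`) so that
every genomic point stays attributable.

## Statistics

* `lineage_counts()`: surviving lineages per integer generation. Under DTWF
  the count may grow at first — a lineage's material can land on both of
  its parent's haplotypes, so at most doubling per generation — but never
  exceeds `2N(t)`. Under Hudson it routinely blows far past `2N` for large
  samples of long genomes and stays above `2N` for thousands of
  generations.
* `extract_ibd()`: genealogical IBD — for each sample pair, maximal
  intervals with a constant MRCA node no older than `max_gen` generations.
  Adjacent same-MRCA intervals are merged even when recorded by different
  edges; records are reported per chromosome (split at boundaries, the
  convention of the analytic expectations and of empirical IBD callers);
  spacer gaps contribute no length; segments shorter than `min_cm` are
  dropped, mimicking the detection floor of real IBD calls. An independent
  brute-force check, `ibd_grid_scan()`, climbs the marginal tree at every
  grid point; the two must agree exactly.
* `ancestry_fractions()`: per-sample migrant genome share at a pulse
  census, plus the across-sample variance.
* `drop_mutations()` / `sfs()`: infinite-sites mutations as a Poisson
  process with mean `mu x genetic span x branch length` per edge, and the
  resulting site frequency spectrum. `sfs_branch()` computes the *expected*
  spectrum given the genealogy (the branch-mode spectrum of the tree-sequence
  world): the same estimand with the mutational noise integrated out, which
  the model-contrast tests use for power.
* `pairwise_r2()`: squared haplotype correlations binned by genetic
  distance, with cross-chromosome pairs in an `"unlinked"` bin — where
  diploid inheritance, but not Hudson's coalescent, predicts excess LD in
  small populations.

## Theory oracles

Three independent routes exist for every headline expectation:

1. **Closed forms.** `expected_ibd(m, a, map, min_len)` models IBD between
   relatives separated by `m` meioses through `a` shared ancestors: point
   IBD probability `a 2^(1-m)`, run ends at crossovers in any of the `m`
   meioses (rate `m` per Morgan), runs truncated at chromosome ends. The
   infinite-chromosome limit is the familiar `a 2^(1-m) (mL + C)` segment
   count with mean excess length `1/m`; the truncation correction matters —
   for half-siblings it lowers the expected total length by ~25%. Because
   observed relative pairs are ascertained by having at least one detected
   segment, detection-conditioned variants (`*_detected`, dividing by
   `1 - exp(-E[n])` under a Poisson count) are also returned; they are the
   right comparison for simulated cohorts and matter greatly for distant
   classes (at `m = 10`, about half of all pairs show no segment at all at
   a 1 cM detection floor).
   `expected_ancestry_variance(f, g, map, N)` comes from a two-locus
   backward co-ancestry chain: two lineages separate by recombination with
   probability `c(d) = (1 - exp(-2d))/2` per generation (1/2 across
   chromosomes) and rejoin with probability `1/(2N)`; the expected
   across-sample variance is `f(1-f)/L^2` times the double integral of
   `(1 - c(d) - 1/(2N))^g`. For unlinked loci and large `N` this is the
   classical genealogical term `f(1-f)/2^g`; the within-chromosome part is
   the recombination variance, decaying like `1/g` and dominating after
   roughly ten generations.
2. **A forward gene-dropping oracle.** `forward_pedigree_oracle()` builds an
   explicit random-mating pedigree (monogamous or not) and drops uniquely
   labelled founder haplotypes through it with *the same meiosis model as
   the DTWF engine* — a deliberate choice so that engine-vs-oracle
   comparisons are about genealogy, not recombination modelling.
   `relative_pair_ibd()` does the same through the minimal pedigree of a
   single relationship. The closed forms above are accepted only because
   they sit inside the oracle's Monte-Carlo confidence bands; the oracle is
   the arbiter wherever the algebra could be transcribed in more than one
   way.
3. **A naive R engine.** The test helpers include a from-scratch, quadratic
   R implementation of Hudson's algorithm built on the exported lineage
   algebra (`new_sample_lineages()`, `apply_recombination()`,
   `merge_lineages()`); the compiled engine must match its event counts and
   bookkeeping on tiny instances.

## Cousin-containment probabilities

`cousin_containment(K, N, p)` asks how often a sampled individual has a
p-th cousin in the sample, under a monogamous Wright-Fisher pedigree. The
cited calculation expects `4^p` p-th cousins per individual and hence
containment `1 - exp(-4^p K/N)` — 55% for first and 96% for second cousins
at `K/N = 0.2`. That expectation assumes perfect binary ancestor trees,
i.e. every couple leaves exactly two children (`model = "fixed"`, the
default, which simulates to 59% / 97% — slightly above the Poisson
approximation because cousins come in sibships). Under natural
Wright-Fisher family sizes (`model = "wf"`) the parents' sibships are
size-biased — your parent's family has on average one extra child — which
doubles the expected cousin count to `2 x 4^p` and raises containment to
~74% / ~98%. Both models are exposed because the difference is a real
modelling choice, not an implementation detail; `method = "closed_form"`
evaluates the cited approximation directly.

## Numerical and design choices

* Intervals are half-open `[left, right)` with exact double comparisons; no
  epsilon is ever used. Breakpoints come from continuous distributions, so
  ties have probability zero; a duplicate draw is simply redrawn.
* One ancestor node per common-ancestor event, even when several disjoint
  intervals coalesce — standard tree-sequence semantics, keeping marginal
  trees consistent across intervals. Simultaneous multi-way DTWF mergers
  create a single (polytomous) node.
* Fully-coalesced intervals are pruned immediately; the grand-MRCA node
  stays in the table. Edges are grouped by parent in non-decreasing time
  order with adjacent same-(parent, child) intervals squashed.
* Parent choice in the DTWF engine is uniform over diploids, non-monogamous
  and without selfing-prevention, so half-siblings are greatly
  over-represented relative to a human cohort (a documented property of the
  model, visible as the isolated high-sharing cluster among IBD pairs);
  monogamy exists only in the oracle and in `cousin_containment()`.
* All randomness flows from the single seed in `sim_config()`; the engines
  draw from R's RNG, so identical configurations reproduce identical
  tables.
* Time-inhomogeneous coalescence under exponential growth uses the
  closed-form inversion of the integrated rate; recombination and migration
  are time-homogeneous between demographic events.

## What the synthetic worlds do and do not establish

The generators emulate idealized randomly-mating populations: constant or
exponentially growing sizes, uniform recombination within chromosomes, no
crossover interference, no sex-specific maps, no assortative mating or
monogamy (except where noted), pulses acting on haploid lineages. Green
tests establish that the two engines realize their respective mathematical
models and that the statistics computed from the recorded genealogies obey
the theory derived for those models. They do not establish realism of any
particular human cohort: family-size variation, monogamy and fine-scale
migration all shift relatedness statistics materially (the cousin-model
contrast above quantifies one such shift at a factor of two).

## Known limitations

* Hudson whole-genome runs are intrinsically heavy: lineage counts far above
  `2N` mean event rates of tens of thousands per generation. The full-scale
  published regimes (10,000 samples, 22 chromosomes, 100,000+ generations)
  are not desk-scale; the test suite runs scaled versions that preserve the
  qualitative claims, and the one long-horizon check (2,000 samples, 4
  chromosomes, to generation 10,000) takes a few minutes.
* The doubleton deficit of the DTWF spectrum is a ~6% effect at `n = 2N`
  and needs a few hundred replicates to detect reliably; 20-replicate
  contrasts have roughly coin-flip power.
* No gene conversion, no SMC-style approximations, no fixed-pedigree
  simulation, no sex chromosomes.
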