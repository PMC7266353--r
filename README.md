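# wfcoal

Whole-genome genealogy simulation under Hudson's coalescent, a backwards
discrete-time Wright-Fisher (DTWF) model, and a hybrid of the two — plus the
multi-locus statistics that expose where the coalescent goes wrong for large
cohorts.

## Why

Hudson's coalescent with recombination treats every recombination event as
the birth of a new, independent ancestral lineage. Over a whole genome this
lets a sample accumulate vastly more simulated ancestors than a diploid
population contains: the number of surviving lineages shoots past the
haploid population size `2N` (up to ~10x for 10,000 whole genomes) and stays
above it for thousands of generations. The casualties are every statistic
that depends on long-range correlations within and across chromosomes:

* close relatives get far too few identity-by-descent (IBD) segments;
* the variance of ancestry proportions shortly after an admixture pulse is
  underestimated by an order of magnitude (the genealogical `f(1-f)/2^g`
  term is simply absent);
* LD between unlinked loci — the signal used to estimate small effective
  population sizes — is missing;
* the site frequency spectrum misses the singleton excess / doubleton
  deficit created by simultaneous multi-way coalescences.

The DTWF model fixes all of this by giving every gamete exactly one diploid
parent: generations are iterated one by one and each lineage's material is
split by one meiosis (Poisson crossovers at the map rate, independent
chromosome assortment) between the two haplotypes of a single uniformly
chosen parent, so the lineage count can never exceed `2N(t)`. A hybrid model
runs DTWF for the recent past — where the distortions live — and the faster
coalescent beyond a switch time.

Both engines are compiled (Rcpp) and record genealogies as node/edge tables;
statistics, closed-form expectations and a forward gene-dropping oracle are
tidyverse-style R on top.

## Worked example: relatives in a small cohort

Simulate 200 haploid genomes (4 chromosomes, ~9.9 Morgans) in a diploid
population of 500 under the DTWF model, stopping 6 generations back, and
extract IBD through ancestors up to 5 generations:

```r
library(wfcoal)

map <- genetic_map(human22_map()$lengths[1:4], spacer = 0.5)
cfg <- sim_config("dtwf", samples = 200, map = map,
                  demography = demographic_model(population(500)),
                  seed = 7, stop_time = 6)
g <- simulate_genealogy(cfg)
g
#> <genealogy> dtwf model: 200 samples, 1341 nodes, 9945 edges, 778 lineages left at t = 6

pairs <- ibd_pair_summary(extract_ibd(g, max_gen = 5, min_cm = 1))
pairs
#> # A tibble: 2,951 x 5
#>   sample_a sample_b n_segments total_cm min_tmrca
#>      <int>    <int>      <int>    <dbl>     <dbl>
#> 1        0        2          1    14.4          4
#> 2        0        3          1    44.2          4
#> ...
```

2,951 sample pairs share at least one >1 cM segment through an ancestor in
the last five generations. The half-sibling cluster (`min_tmrca == 1`; the
engine is non-monogamous, so half-sibs abound) matches the closed-form
expectation for relatives separated by `m = 2` meioses through `a = 1`
shared ancestor:

```r
expected_ibd(m = 2, a = 1, map, min_len = 0.01)[, 1:5]
#> # A tibble: 1 x 5
#>       m     a min_len expected_n expected_total_cm
#> 1     2     1    0.01       11.6              496.

half_sibs <- dplyr::filter(pairs, min_tmrca == 1)
c(pairs = nrow(half_sibs), segments = mean(half_sibs$n_segments),
  total_cm = mean(half_sibs$total_cm))
#> pairs = 36, segments = 12.2, total_cm = 505
```

36 half-sib pairs average 12.2 segments totalling 505 cM against an
expectation of 11.6 segments / 496 cM. Under `model = "hudson"` the same
comparison collapses — close relatives show far too few segments — which is
the core qualitative contrast the package reproduces, alongside lineage
counts (`lineage_counts()`, `plot_lineage_counts()`), admixture ancestry
variance (`ancestry_fractions()`, `expected_ancestry_variance()`), spectra
(`drop_mutations()`, `sfs()`, `sfs_branch()`) and long-range LD
(`pairwise_r2()`).

## Validation layout

Every expectation has at least two independent routes: closed forms
(`expected_ibd()`, `expected_ancestry_variance()`, cousin-containment), a
forward gene-dropping pedigree oracle (`forward_pedigree_oracle()`,
`relative_pair_ibd()`) sharing only the meiosis model with the DTWF engine,
and — for the engines themselves — a naive quadratic R implementation of
Hudson's algorithm in the test helpers. `tests/testthat/test-acceptance.R`
holds one block per headline claim (lineage-count cap and explosion, cousin
probabilities, ancestry variance, the IBD surface, the SFS shift, TMRCA
laws, hybrid degeneracies, the IBD grid-scan oracle, and a long-horizon
lineage-count run).

`scripts/acceptance.R` recomputes the quantitative headline numbers from
scratch against the installed package — monogamous-pedigree cousin
containment at `K/N = 0.2` and the DTWF/Hudson ancestry-variance ratio after
a 30% pulse — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/wfcoal-methods.Rmd`) documents the models,
the event-timing and coordinate conventions, the spacer subtlety for
cross-chromosome statistics, and the known limitations.
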