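# ecosig

Phage **eco**genomic **sig**natures for microbial source tracking in viral
metagenomes.

Faecal pollution of water is traditionally monitored with culture-based
faecal indicator bacteria, which say little about *whose* faeces are
present. Gut-specific bacteriophages offer an alternative: the per-gene
representation of a gut phage's ORFs across a metagenome — its *ecogenomic
signature* — is habitat-specific, so the signature recovered from an
environmental virome can reveal both the presence of faecal pollution and
its host source (human vs animal). `ecosig` implements that analysis as a
reusable pipeline for anyone working with homology-search profiles of viral
metagenomes: environmental microbiologists evaluating virome-based source
tracking, and method developers who need a tested reference implementation.

## What it computes

* **Profiles.** Hit tables (12-column tabular output of BLAST-style
  searches) are filtered with the validity rule *identity ≥ 35%, query
  coverage ≥ 50%, e-value ≤ 1e-5* (all inclusive) and converted to per-ORF
  relative abundances in hits per megabase:
  `a_i = n_i / (total_bp / 10^6)`, with multiple HSPs per (query, ORF) pair
  collapsed to the best one. Cumulative relative abundance is the sum of
  `a_i` over any ORF subset.
* **Ordination.** Square-root transform, Bray–Curtis dissimilarity
  `d(u,v) = Σ|u_i − v_i| / Σ(u_i + v_i)`, non-metric multidimensional
  scaling (best of *n* random starts, Kruskal stress-1 via SMACOF +
  isotonic regression), and ANOSIM
  `R = (r̄_between − r̄_within) / (M/2)` with permutation p-values
  (`(1 + #{R_perm ≥ R_obs}) / (1 + n_perm)`), including an exact
  enumeration mode for small n.
* **Pollution simulation.** In silico contamination
  `out_i = env_i + s · source_mean_i` at strengths `s ∈ [0, 1]` (the percent
  convention maps 100% ↦ 1), dilution series over a decade grid, and a
  Monte-Carlo simulation in which permuted environmental baselines are drawn
  per ORF from `Uniform[0, max_i]` and polluted at `Uniform[0, 1]` strengths
  with human, bovine or porcine source signatures.
* **Classification.** ROC curves (score = cumulative abundance over an ORF
  subset; positive iff score ≥ threshold), threshold selection maximising
  specificity under a minimum-sensitivity constraint (default 0.91), and a
  two-step classifier: step 1 calls pollution, step 2 attributes it to a
  human source, with per-type accuracy, SEM over iterations, and pooled
  sensitivities/specificities.
* **Group statistics.** Shifted log transform `log10(y + 1e-5)`,
  Kruskal–Wallis with tie correction, Dunn's post-hoc comparisons with
  Bonferroni-family adjustment, and a per-ORF habitat-affiliation table
  that flags gut-affiliated ORF subsets.
* **Synthetic data.** A zero-inflated lognormal cohort generator with
  habitat-structured ORF archetypes, and hit-table fixture generation that
  round-trips *exactly* through the profiling stage.

## Worked example

Simulate a habitat-structured world, run the Monte-Carlo pollution
simulation, calibrate the two-step classifier on iteration 1 and evaluate it
on the remaining nine iterations:

```r
library(ecosig)

cohort <- generate_cohort(cohort_spec(seed = 42))
cohort
#> profile_matrix: 48 data sets x 70 ORFs
#>   groups: bovine_virome (12), env_virome (12), human_gut_virome (12), porcine_virome (12)

world <- mc_world_from_cohort(cohort)
cfg <- monte_carlo_config(world$env_max, world$source_means,
                          n_iterations = 10, n_env_per_iteration = 100,
                          n_polluted_per_type = 100, seed = 42)
iterations <- run_monte_carlo(cfg)

it <- iterations[[1]]
d <- bray_curtis(sqrt_transform(it$profiles))
anosim(d, ifelse(it$labels$type == "ENV_U", "uncontaminated", "polluted"),
       n_permutations = 999, seed = 42)
#> ANOSIM: R = 0.9162, p = 0.001 (999 permutations)

model <- calibrate_two_step(it)
model
#> two-step model:
#>   step 1 (subset1, 15 ORFs): polluted iff score >= 0.8509
#>   step 2 (subset2, 3 ORFs): human iff score >= 1.117

evaluate_iterations(iterations[-1], model)
#> two-step classification performance
#>   ENV_U    accuracy 1.000 (SEM 0.000)
#>   ENV_HGV  accuracy 0.988 (SEM 0.007)
#>   ENV_BOV  accuracy 1.000 (SEM 0.000)
#>   ENV_PORC accuracy 0.994 (SEM 0.002)
#>   pooled step-1 sensitivity 0.998, specificity 1.000
#>   pooled step-2 sensitivity 0.988, specificity 1.000
```

The ANOSIM R near 1 says polluted and uncontaminated simulated viromes are
almost completely separated in Bray–Curtis space; the performance table
says the calibrated thresholds generalise to held-out iterations: virtually
all uncontaminated permutations are recognised as such, and human pollution
is distinguished from bovine/porcine pollution in ~99% of data sets.

The published gut-affiliated subsets of the *Bacteroides* phage B124-14
genome are available as `subset1_orfs()` (15 ORFs, pollution detection) and
`subset2_orfs()` (ORFs 16, 34, 56; human attribution); `orf_affiliation()`
reproduces such subsets from labelled profile matrices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the given seed: the ANOSIM permutation
p-value separating each simulated polluted group from uncontaminated
permuted environmental viromes (one-iteration Monte-Carlo, 100 data sets
per group, 999 permutations), and the pooled step-1 sensitivity of the
two-step classifier on nine held-out iterations after ROC calibration on
iteration 1. Results are written as JSON to `--out`.

## Vignette

`vignettes/source-tracking.Rmd` documents the model, the simulation design,
the generator's assumptions, numerical choices and known limitations.
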