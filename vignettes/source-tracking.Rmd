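---
title: "Virome-based microbial source tracking with phage ecogenomic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virome-based microbial source tracking with phage ecogenomic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecosig)
```

## The problem

Faecal contamination of environmental water is usually detected with
culture-based faecal indicator bacteria, which are poor at telling a human
source from an animal one. Gut-adapted bacteriophages provide an
alternative marker: because a gut phage's genes are enriched in gut
communities and largely absent elsewhere, the pattern of per-gene
representation of such a phage across a metagenome — its *ecogenomic
signature* — carries habitat information. `ecosig` implements the full
analysis chain: building per-ORF abundance profiles from homology-search
output, testing habitat separation by ordination, simulating faecal
pollution in abundance space, and classifying viromes as unpolluted,
human-polluted or non-human-polluted.

## Abundance profiles

The unit of observation is the relative abundance of one phage ORF in one
metagenomic data set,

$$ a_i = \frac{n_i}{\mathrm{total\_bp} / 10^6} \quad \text{(hits/Mb)}, $$

where $n_i$ counts *valid* homology-search hits assigned to ORF $i$. A hit
is valid when all three of the published criteria hold, inclusively:
identity $\ge 35\%$, query coverage $\ge 50\%$ (computed as
$(q_\mathrm{end} - q_\mathrm{start} + 1)/q_\mathrm{len}$ on 1-based
inclusive coordinates), and e-value $\le 10^{-5}$. Which side of the
alignment is "the query" depends on the search design, so
`read_hit_table()` records an `orientation`: viral data sets are searched
by mapping reads against translated ORFs (reads are queries), whole
community assemblies by searching with the ORF protein (the ORF is the
query). Coverage is always measured on the query side.

Two conventions deserve mention because the hit-table format does not fix
them:

* multiple HSPs between the same (query, ORF) pair are collapsed to the
  single best alignment (lowest e-value, ties broken by higher bit score)
  *before* filtering, so repeated alignments of the same pair can never
  inflate a count;
* a query validly hitting $k$ distinct ORFs contributes one count to each
  of them, since abundance is computed per ORF independently. The
  alternative reading — credit only the single best ORF — is available as
  `best_orf_only = TRUE` in `compute_profile()`.

Data set sizes (`total_bp`) come from the metadata table rather than from
raw sequence files; the package deliberately does not consume reads.
Cumulative relative abundance is the plain sum of $a_i$ over an ORF subset,
and the stringency filter `filter_min_orf_representation()` drops data sets
detecting fewer than two distinct ORFs before any ordination.

## Ordination and ANOSIM

Profiles are square-root transformed, then converted to Bray–Curtis
dissimilarities $d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)$. A pair
of all-zero profiles has an undefined ratio; it is assigned distance 0 with
a warning, which can only arise for data sets that the two-ORF stringency
filter would have removed anyway.

`nmds()` minimises Kruskal's stress-1,

$$ \sigma_1 = \sqrt{\frac{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}
                        {\sum_{i<j} d_{ij}^2}}, $$

where $d_{ij}$ are configuration distances and $\hat d_{ij}$ the
disparities from isotonic regression of $d$ on the rank order of the input
dissimilarities. Each start alternates isotonic regression with a
Guttman-transform (SMACOF) update; the best of `n_starts` random starts is
returned (default 1000, the stringent published setting — reduce it for
exploratory work). Ties in the input dissimilarities receive the *primary*
treatment (within a tie block the disparities follow the configuration), as
in standard ecological software. A caution inherited from stress-1 itself:
for small or strongly clustered inputs the global optimum can be a
degenerate clustered configuration with near-zero stress; we verified that
vegan's `monoMDS` behaves identically on such inputs, and on
habitat-structured cohorts both engines produce conventional solutions.

`anosim()` uses Clarke's statistic
$R = (\bar r_B - \bar r_W)/(M/2)$ with $M = n(n-1)/2$ pairwise
dissimilarities ranked with mean ranks for ties; $R$ approaches 1 under
complete separation and 0 under no structure. Significance comes from
random relabelling with $p = (1 + \#\{R_\pi \ge R\})/(1 + n_\pi)$, so the
smallest attainable p-value with the default 999 permutations is 0.001 (the
permutation count is configuration: the analysis it follows reports
p = 0.001-level significance but not its permutation count). For $n \le 8$,
`n_permutations = "exact"` enumerates every distinct relabelling, and the
test suite verifies exact agreement with a brute-force oracle.

## Simulated pollution

Contamination acts in abundance space, gene by gene:
$\mathrm{out}_i = \mathrm{env}_i + s \cdot \mathrm{source}_i$, where
$\mathrm{source}$ is the mean profile of a source habitat (e.g. the average
over 12 human gut viromes, the published human-gut cohort size used by the
generator's defaults) and $s \in [0,1]$ is the strength; all I/O accepts
the percent convention (100% $\leftrightarrow$ 1). The dilution-series
helper uses decade steps $\{1, 0.1, 0.01, 0.001, 10^{-4}\}$ spanning the
published 100%–0.01% range; only the endpoints of that range are stated, so
the grid is a configuration default, not a reproduced fact. No sequencing
noise is added to contaminated profiles — contamination is defined on
abundances.

The Monte-Carlo simulation generalises the fixed environmental backgrounds:
each permuted environmental profile draws every ORF independently from
$\mathrm{Uniform}[0, \max_i]$, where $\max_i$ is the largest abundance of
ORF $i$ across environmental viromes, and each polluted data set adds a
source signature at a strength drawn from $\mathrm{Uniform}[0, 1]$. Per
iteration the default produces 100 uncontaminated permutations (ENV^U) and
100 polluted data sets for each of the human (ENV^HGV), bovine (ENV^BOV)
and porcine (ENV^PORC) signatures, over 100 iterations — the published
design. Two modelling choices are deliberate: ORFs are permuted
independently (inter-ORF correlation of real environmental backgrounds is
not modelled, and is unknowable from the published description), and every
polluted data set is built on a *freshly* permuted baseline rather than
reusing an ENV^U member, keeping the groups independent.

## The two-step classifier

Classification scores are raw cumulative abundances over an ORF subset —
no transform, since the square root and log transforms belong to
ordination and group statistics respectively. Prediction is positive iff
score $\ge$ threshold; the orientation is fixed by the fact that pollution
adds abundance.

ROC curves sweep the distinct observed scores plus $\pm\infty$, and the
trapezoidal AUC equals the probability that a random positive outscores a
random negative, ties counted one half (the suite checks this identity
exactly). `select_threshold()` implements the published rule: among
operating points with sensitivity $\ge 0.91$, take the one with maximal
specificity (ties resolved toward higher sensitivity, then higher
threshold).

Calibration follows the published split: a single iteration builds both ROC
curves — step 1 on subset-1 scores (any polluted type vs ENV^U), step 2 on
subset-2 scores (ENV^HGV vs the other polluted types, among truly polluted
data sets) — and all remaining iterations evaluate the fixed thresholds.
Thresholds are selected once on the calibration iteration, not re-selected
per evaluation iteration; `calibrate_two_step()` can simply be called on
another iteration if per-iteration calibration is wanted. Evaluation
reports, per true type, the proportion correctly classified with mean and
SEM across iterations (SEM 0 by convention for a single iteration), plus
pooled step-1 and step-2 sensitivities/specificities; step-2 rates are
computed among truly polluted data sets that passed step 1, since only
those reach step 2.

## Per-ORF habitat affiliation

`orf_affiliation()` reconstructs gut-affiliated subsets from labelled
profile matrices. Group means are reported on the shifted log scale
$\log_{10}(y + 10^{-5})$ — the pseudocount maps absent ORFs to $-5$ — while
the tests operate on pooled ranks: the transform is strictly monotone, so
the Kruskal–Wallis H (tie-corrected, $\chi^2_{k-1}$ approximation) is
identical on raw and transformed values, and the suite asserts that
identity exactly. Dunn's pairwise z-statistics use the pooled-rank variance
with tie correction; adjusted p-values multiply by the number of pairwise
comparisons and cap at 1 (the Bonferroni-family convention of the
commercial analysis software this mirrors; Holm is available). Flags
require three things at level $\alpha = 0.05$: a significant omnibus
Kruskal–Wallis test (post-hoc comparisons are conditional on the omnibus,
the standard convention), a Dunn-adjusted pairwise p $\le \alpha$, and the
focal group's mean actually exceeding the comparison group's. An ORF
significantly above the environmental group is a *subset-1 analogue*; one
above every other group is a *subset-2 analogue*; ORFs detected in at least
half of all data sets are flagged cosmopolitan.

## The synthetic cohort generator

No public per-ORF profile matrices accompany the analysis this package
implements, so every end-to-end test runs on synthetic cohorts whose
structure states the assumptions explicitly. Each ORF gets an archetype:

| archetype | where elevated | defaults |
|---|---|---|
| `human_gut_specific` | human gut viromes only | ORFs 16, 34, 56 (the subset-2 ids) |
| `gut_shared` | all gut viromes | the remaining subset-1 ids |
| `cosmopolitan` | everywhere, moderately | ORFs 1–4, 6–11 |
| `background` | sparse and weak everywhere | all others |

Abundances are zero-inflated lognormal: present with probability
`occurrence`, and then lognormal with median `mean_abundance` (hits/Mb) and
dispersion `sdlog`. The defaults (e.g. human-gut-specific ORFs: occurrence
0.9, median 20 hits/Mb, sdlog 1 in human gut viromes vs 0.05/0.05/1 in
environmental viromes) were chosen once to reproduce the qualitative
features the analysis depends on — sparse environmental background,
gut-enrichment of the planted subsets, high inter-individual variability of
gut viromes (sdlog 1 spans roughly an order of magnitude either way) — and
they produce the ordering human gut > animal gut > environmental in mean
cumulative abundance, which the suite asserts. The lognormal family itself
is an assumption: the true marginal distribution of per-ORF abundances in
real data is unpublished. A green test on these cohorts establishes that
the *pipeline* behaves as specified under the stated world; it does not
certify performance on real viromes, where background correlation
structure, sequencing noise and unmodelled habitats all enter.

`generate_hit_table_fixture()` closes the loop on the profiling stage: for
any profile matrix with rational entries it emits hit tables whose valid
rows sit *exactly on* the filter boundaries (identity 35.0, coverage 0.50,
e-value 1e-5) plus decoys violating exactly one criterion each (34.9, 0.49,
1.1e-5), choosing `total_bp` so hit counts are integers. An exact round
trip therefore certifies the counting, the normalisation and the
inclusiveness of all three thresholds at once.

## Numerical choices and degenerate inputs

* ANOSIM divisor $M/2$ (Clarke's definition, verified against vegan); mean
  ranks for ties; p-value estimator $(1+c)/(1+n)$ avoids $p = 0$. All
  dissimilarities identical yields $R = 0$ with a warning.
* nMDS convergence when the stress change drops below `tol` (default 1e-6)
  or `max_iter` (300); the returned configuration is centred. Defaults keep
  1000-start runs tractable at $n \le 300$.
* Kruskal–Wallis on all-identical values returns $H = 0$, $p = 1$ with a
  warning instead of dividing by a zero tie correction.
* Thresholds in `is_valid_hit()` and `two_step_classify()` are inclusive
  exactly as printed; `select_threshold()` tie-breaks are deterministic.
* Seeds are explicit arguments everywhere randomness occurs; no function
  consumes hidden global state beyond R's RNG when a seed is supplied.

## Known limitations

* The package starts from hit tables; running the homology search and
  translating ORFs are out of scope.
* Real-data figures of the analysis this package implements (profiles over
  hundreds of public metagenomes) are not reproducible without those data
  sets; the test suite covers the machinery with synthetic cohorts and
  brute-force oracles instead.
* Monte-Carlo baselines ignore inter-ORF correlation, and contamination is
  noiseless addition in abundance space — both inherited from the
  simulation design being implemented.
* Stress-1 nMDS can return degenerate near-zero-stress solutions for tiny
  or perfectly clustered distance matrices (a property of the objective,
  shared with vegan); inspect the configuration, not only the stress.
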