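---
title: "Y-STR haplotype diversity and population differentiation with ystrpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR haplotype diversity and population differentiation with ystrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrpop)
```

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are transmitted patrilineally
without recombination, so the joint allele vector over a locus panel — the
haplotype — behaves as a single, male-line-inherited allele. Forensic
laboratories genotype panels such as the 17-column Yfiler multiplex (16
loci; the duplicated locus DYS385 contributes an unordered a/b pair) and
summarise a population sample with a small set of statistics:

* **Gene diversity (GD)** per locus: Nei's unbiased estimator
  $\hat H = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$,
  the probability that two randomly drawn allele copies differ, corrected
  for sample size.
* **Haplotype diversity (HD)**: the same estimator applied to
  whole-haplotype frequencies.
* **Discrimination capacity (DC)**: the number of distinct haplotypes
  divided by the number of haplotypes sampled.
* **Haplotype match probability (HMP)**: $1 - \mathrm{HD}$, the chance two
  random males share a haplotype.
* **Pairwise $F_{ST}$** between populations from a two-level analysis of
  molecular variance (AMOVA), with permutation p-values, and a classical
  multidimensional scaling (MDS) embedding of the resulting distance
  matrix.

`ystrpop` implements this pipeline end to end on tabular haplotype data,
together with a forward-time Wright–Fisher simulator that generates
synthetic multi-population tables with the same statistical structure, so
every stage can be validated without access to any study's raw donor data.

## Data model and validation

A dataset is one row per donor: `sample_id`, `population`, and 17 numeric
allele columns in repeat units. Three rules are enforced at construction
rather than at analysis time:

* the DYS385 pair is stored sorted ascending, whatever order it arrived
  in, and haplotype keys are built on the sorted pair — two donors match
  iff all 17 values match, treating DYS385 as an unordered pair;
* microvariant alleles (e.g. 13.2) are exact decimals and compare
  exactly; allele identity is categorical in forensics, so no tolerance
  is ever applied;
* out-of-range calls are flagged, never silently dropped, and rows with
  missing calls are excluded from haplotype-level statistics while their
  clean loci still contribute to per-locus GD (this maximises locus-level
  information from partial profiles).

DYS389II is stored as reported by the kit (no subtraction of DYS389I),
matching the kit's published allele ranges. Published 17-row listings of
the Yfiler panel often count DYS456 twice; the built-in panel keeps the 16
distinct loci and lets DYS385's two columns supply the 17th value.

## AMOVA, $F_{ST}$ and permutation significance

Two distance models are offered. The default, `identity`, scores two
haplotypes 0 if identical and 1 otherwise, which makes the AMOVA
$\Phi$-statistic a haplotype-frequency $F_{ST}$ — the convention used by
haplotype reference databases. The alternative, `stepwise`, sums absolute
repeat differences (minimum-assignment over the two pairings for the
unordered DYS385 pair), giving an $R_{ST}$-like statistic that weights
multi-step differences. Sums of squares use squared model distances, the
standard variance-component convention.

The two-level decomposition follows the classic recipe: with $N$
haplotypes in $k$ populations,
$SS_{total} = \tfrac1N\sum_{i<j} d^2_{ij}$, within-population sums use the
same form per group, $\sigma^2_w = SS_w/(N-k)$,
$\sigma^2_a = (SS_a/(k-1) - \sigma^2_w)/\bar n$ with
$\bar n = (N - \sum_g n_g^2/N)/(k-1)$, and
$\Phi = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$. Negative $\Phi$ estimates
(sampling noise around zero differentiation) are reported as computed in
tables, and clamped to zero only where MDS needs non-negative
dissimilarities. If the input carries no variation at all, $\Phi$ is
defined as 0 and flagged degenerate rather than left 0/0.

Permutation p-values reassign individuals to the two population labels,
holding sizes fixed, and use the add-one rule
$p = (1 + \#\{\Phi^\ast \ge \Phi\})/(B+1)$, so $p \ge 1/(B+1)$ and a
literal zero can never be reported. The seed is mandatory. No
multiple-testing correction is applied to the matrix itself; the report
writes a Bonferroni-adjusted copy alongside so users can choose. The MDS
axes have deterministic signs (largest-magnitude coordinate positive) so
plots reproduce across machines.

## The synthetic-data generator

`simulate_dataset()` runs a discrete-generation haploid Wright–Fisher
process: `k` demes of constant size `Ne` patrilines; each offspring draws
its father from its own deme with probability $1-m$ and from a uniformly
chosen *other* deme otherwise; each allele copy then mutates with
probability `mu` under the stepwise mutation model (±1 full repeat,
reflecting at the panel bounds, so microvariant fractional parts are
carried through, not generated). DYS385 is simulated as two independently
mutating copies and sorted only on output, matching the data model.
Patriline identities are tracked, and the truth log records the realised
full-deme allele frequencies and surviving founder-lineage counts.

Two founding modes exist. The default single founder haplotype (panel
midpoints) gives the classic mutation–drift build-up. Alternatively,
`founder_freqs` seeds each column with i.i.d. draws from a specified
allele distribution. The second mode exists because reaching
mutation–drift equilibrium from a monomorphic founder takes on the order
of the total coalescent time (thousands of generations for realistic
diversity), whereas seeded standing variation reproduces target diversity
levels immediately; the packaged fixtures use it with per-column
discretised double-geometric distributions whose spread is solved
numerically to hit a target GD.

With two demes and migrants drawn from the opposite deme, the
migration–drift balance satisfies $F_{ST} = 1/(1+4N_e m)$ in the
weak-mutation limit (the familiar island-model result; with migrant pools
defined this way no finite-island correction factor is needed). The test
suite exploits this as a parameter-recovery check: simulations at
$4N_e m \in \{1, 19, 99\}$ must recover the analytic expectation. Mutation
is tied to migration there (`mu = m/500` per locus, i.e. a haplotype-level
rate of $0.034\,m$) so its extra homogenising term biases the expectation
by under 2%, and the aggregate estimate is the ratio of summed variance
components across replicates — the standard multilocus convention, which
stays well defined even when single replicates carry little polymorphism —
with a delete-one jackknife standard error.

### The `iran-like` fixture

`make_fixture("iran-like")` emulates a 16-province national survey:
population labels and sample sizes 27–236 summing to N = 1353, nearly all
haplotypes unique, and pooled per-locus GD spanning roughly 0.3–0.9 with
DYS391 least and DYS385 most polymorphic. Two of its parameters deserve
comment:

* **Deme size.** The profile uses `Ne = 50000` with 3 drift generations.
  A small deme cannot produce an almost-all-unique sample: drawing
  $n$ donors from a deme of size $N_e$ yields roughly
  $\binom{n}{2} t/N_e$ shared patrilines after $t$ generations
  (~80,000 within-province pairs here), so $N_e \le 500$ would force
  hundreds of duplicate haplotypes. A large deme observed over a short
  window is also the honest miniature of a real patrilineal population,
  whose effective size is effectively infinite on this timescale. Other
  profiles and all recovery experiments keep small `Ne`, where drift is
  the object of study.
* **Diversity targets.** Initial per-column GD targets (0.34–0.87) were
  chosen once to span the band typical of Y-STR surveys and are preserved
  over the short drift window; the realised pooled values are recorded in
  the fixture's truth log. Per-province GD cells at $n$ as small as 27
  carry sampling noise of about ±0.1, so the 0.3–0.9 band is a property
  of the pooled (national) estimates, not of every cell.

What the generator does **not** emulate: real mutation-rate heterogeneity
beyond a per-column scalar, population growth, social structure
(patrilocal clustering, surname effects), genotyping dropout and
microvariant genesis. Passing tests therefore demonstrate estimator
correctness and pipeline integrity, not that any real population behaves
like the fixture.

## Numerical choices

* Diversity estimators are undefined below two gene copies and raise an
  error rather than returning 0.
* Permutation ties count as exceedances (with a $10^{-12}$ guard), the
  conservative direction.
* The reporting profile rounds HD to 5 d.p., DC and GD to 3 d.p., HMP and
  FST to 4 d.p. — the precisions customary in forensic reports — while
  every returned object keeps full precision.
* AMOVA's internal identity $SS_{total} = SS_{among} + SS_{within}$ and
  the independent brute-force decomposition agree to $10^{-9}$ in tests;
  MDS reproduces exactly Euclidean matrices to $10^{-9}$.
* Problem sizes used by the validation suite (chosen as desk-scale
  defaults: two demes with `Ne` scaled per case as `max(100, 50 * 4Nem)`
  so migration stays in the weak regime, 400–600 generations, 50 donors
  sampled, 200 replicates for recovery; 200 null replicates at B = 999
  for p-value calibration) keep the full suite within a coffee break
  while leaving Monte-Carlo error well below the effects tested.

## A worked example

```{r example, eval = FALSE}
library(ystrpop)

ds <- make_fixture("tiny")          # 3 populations x 10 donors
diversity_summary(ds)

fst <- pairwise_fst_matrix(ds, B = 999, seed = 1)
fst$values
classical_mds(fst, m = 2)$coordinates

out <- run_report(ds, "report_out", B = 999, seed = 1)
```

For shell use, the same pipeline is exposed as
`Rscript $(Rscript -e 'cat(system.file("scripts","ystrpop.R",package="ystrpop"))') report --input table.tsv --out report_out --seed 1`.

## Known limitations

* Three-level hierarchical AMOVA (provinces within zones) is out of
  scope; only the two-level decomposition is provided.
* The identity/stepwise distance models are the only two offered; no
  molecular-weighted or multi-step mutation distances.
* HD/DC comparisons across studies depend on panel size and sample size;
  the package computes, it does not harmonise.
* The simulator is haploid and patrilineal by design and is not a
  general-purpose population-genetics engine.
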