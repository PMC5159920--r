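---
title: "Discovering ultrasensitive dose-response genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering ultrasensitive dose-response genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ultrahill)
library(dplyr)
```

## The problem

A growth factor applied to cells over a dose series induces genes with very
different response shapes: some ramp up gradually (Michaelian), some switch
on sharply above a threshold (ultrasensitive), some are repressed, and a few
peak or dip at intermediate doses. For synthetic-biology applications —
borrowing a native promoter to drive a switch-like circuit — the
ultrasensitive activators are the interesting class, and the practical
question is how to find them in a replicated FPKM expression matrix over a
handful of doses.

`ultrahill` implements that discovery pipeline end to end: staged filtering
to a responsive gene set, shape classification, Bayesian Hill-function
fitting by Metropolis-Hastings MCMC, and candidate selection, together with
a synthetic-cohort generator that provides ground truth for every stage.

## The dose-response model

The central object is the four-parameter Hill function

$$f(x) = a + b\,\frac{x^{n}}{k^{n} + x^{n}}$$

with basal expression $a$ (FPKM), dynamic range $b$ (maximum minus basal),
half-maximal dose $k$ (ng/ml) and Hill coefficient $n$. The apparent Hill
coefficient measures steepness without mechanistic commitment: $n > 1$ is
ultrasensitive (thresholding, steep transition, saturation), $n = 1$
Michaelian, $n < 1$ negative cooperativity. `hill()` evaluates the ratio in
log space, `plogis(n (\log x - \log k))`, so curves with $n$ of 76 — the
steepest regime we expect to encounter empirically — or even the prior
ceiling of 100 evaluate without overflow; $x = 0$ is short-circuited to
$a$ exactly, so a zero dose needs no pseudodose.

The default dose grid is the two-fold dilution series
$\{0, 1.0, 2.1, 4.2, 8.3, 16.7\}$ ng/ml with two biological replicates —
six conditions, twelve observations per gene.

## The filter tree

Four stages, each a single rule, each auditable (`run_filter_tree()`
returns a ledger in which every input gene sits in exactly one bucket):

1. **Non-zero**: FPKM $> 0$ in at least one cell.
2. **Detectable**: replicate-mean FPKM $> 1$ in at least one condition.
   1 FPKM is roughly one mRNA per cell, a standard detectability anchor.
   The rule is evaluated across all six conditions by default; a
   `scope = "treated"` switch restricts it to stimulated conditions, since
   the two readings are both defensible.
3. **Dose response**: Kruskal-Wallis across the six dose groups at
   $p < 0.33$. The test is the omnibus rank test (`stats::kruskal.test`,
   tie-corrected H, chi-squared p with 5 df). The permissive threshold is
   deliberate — the stage is a discovery sieve, not an inference, and no
   multiple-testing correction is applied anywhere in the tree. A
   `kw_mode = "pairwise_min"` switch instead tests each treated dose
   against dose zero and keeps the smallest p. With two observations per
   group the chi-squared approximation is rough: against the exact
   permutation distribution the p-value can deviate by up to about 0.17,
   which the `small_groups` flag and the documentation state explicitly;
   at the 0.33 threshold this looseness costs little.
4. **Replicate consistency**: one-sided test for positive Pearson
   correlation between the two replicate dose vectors, keep at $p < 0.1$.
   Small p = reproducible response; this is the only reading under which
   the stage excludes highly-variable genes rather than reproducible ones.
   Correlation is computed on raw FPKM by default (`log_scale` switch
   available); genes with a constant replicate vector have no defined
   correlation and get a distinct ledger label.

## Shape classification

Profiles are replicate-averaged and max-normalised (`normalize_profiles()`),
so every gene peaks at exactly 1 and only shape matters. Classification is
a deterministic per-gene rule (`classify_profile()`) with tolerance
$\varepsilon = 0.05$: increase if every step $\ge -\varepsilon$; decrease
if every step $\le \varepsilon$; stripe if the global maximum is interior
and both ends sit below $\max - \varepsilon$; antistripe dually; ambiguous
otherwise, with ties broken increase > decrease > stripe > antistripe.
Constant profiles therefore classify as increase and carry a `flat_flag`.

We deliberately made classification a rule rather than reading classes off
the dendrogram: a clustering cut is not a reliable four-class oracle, and a
rule is reproducible and testable. Hierarchical clustering (squared
Euclidean distances, average linkage by default, flat labels cut at
linkage distance 4) is retained for reporting and ordering, with Ward
linkage available where a variance-style criterion is preferred. The PCA
report (centered SVD of the gene-by-condition matrix) provides the usual
biplot of component scores and condition loadings.

$\varepsilon = 0.05$ on max-normalised profiles absorbs replicate noise of
roughly the same relative size; $\varepsilon = 0$ gives strict
monotonicity. Raising $\varepsilon$ can only move genes *into* the
monotone classes, never out of them — a tested invariant.

## Hill fitting by Metropolis-Hastings MCMC

For each increase-class gene the twelve (dose, FPKM) observations — both
replicates as separate points — are fitted with a random-walk
Metropolis-Hastings sampler (`mh_fit()`, 100,000 steps by default).

**Likelihood.** Gaussian residuals between `log1p`-transformed
observations and model. Candidate genes span 0 to several hundred FPKM
and replicate scatter is multiplicative, so a log-type scale is the
natural choice; `log1p` additionally handles exact zeros. A raw-scale
Gaussian option exists. The noise scale $\sigma$ is, by default, a fifth
chain coordinate under a weak half-normal prior; it can be fixed instead.
For exactly noiseless (synthetic oracle-validation) data a sampled
$\sigma$ collapses to its lower bound and freezes the walk, so the
noiseless checks fix $\sigma = 0.05$, which makes the posterior maximum
coincide with the least-squares optimum.

**Priors and transform.** The chain lives on
$(\log(a + 0.01), \log b, \log k, \log n, \log\sigma)$ with flat priors
inside data-driven bounds: $a \in [0, \max y]$,
$b \in (0, 10 \max y]$, $k \in [\min_{+}x/10,\ 10\max x]$,
$n \in [0.1, 100]$ (the ceiling accommodates the steepest observed
responses), $\sigma \in [10^{-3}, 10]$. Flat-in-log is weakly informative
for scale parameters and keeps the proposal geometry simple.

**Adaptation and burn-in.** Per-parameter proposal scales start at 0.15
and are rescaled every 100 steps toward ~30% acceptance during the first
`min(10000, burn_in)` steps, then frozen, so the retained chain has fixed
proposals and detailed balance. The first 20% of the chain is discarded
by default; `burn_in_fraction = 0` keeps every sample (and disables
adaptation), reproducing the literal whole-chain summaries some analyses
prefer. An acceptance rate outside $[0.05, 0.8]$ raises a warning, not an
error — on noiseless data low acceptance is expected and benign.

**Summaries.** Point estimates are marginal posterior modes (kernel
density argmax); the fit also records the joint MAP sample, the chain
state with the highest log posterior, which is the correct analogue of a
least-squares optimum when validating against the brute-force
`grid_oracle()`. The Hill coefficient additionally gets a binned mode:
histogram bins of width 0.5 anchored at zero, ties broken toward the
lower bin (conservative for the ultrasensitivity call), reported as the
bin midpoint. A gene is called ultrasensitive when the binned mode
exceeds 1, i.e. the modal bin lies entirely above 1. Genes with constant
observations return an `unidentifiable` flag instead of a fit.

**Known limitations.** Parameters are only weakly identified when the
half-maximal dose falls outside the sampled dose range (especially below
the lowest positive dose) or when the transition falls entirely between
two adjacent doses at high $n$; posterior intervals widen accordingly and
the binned mode should be read as an *apparent* Hill coefficient
throughout. Convergence diagnostics are limited to the acceptance rate
and the log-posterior trace; there is no multi-chain $\hat R$ by design —
single-chain behaviour is part of the procedure being reproduced.

## Candidate selection

From the fitted increase-class genes, candidates must (i) be
ultrasensitive (binned-mode $n > 1$), (ii) have log2 fold change between
the top and zero dose of at least 0.7 (replicate means, pseudocount 0.1
FPKM — one order below the detectability cutoff — so zero-basal genes
stay finite), and (iii) have basal FPKM below 50 in at least one
replicate at dose zero, because apparent Hill coefficients of high-basal
responses carry little physiological meaning. Output is ordered by
descending Hill coefficient then fold change, replacing manual shortlist
curation with a deterministic ranking (`top` gives a shortlist). A
separate "off-to-on" report (`low_basal_high_fc()`) lists genes rising
from below 1 FPKM basal to a log2 fold change above 1.7; the 1.7 is read
on the log2 scale for consistency with the 0.7 threshold (a linear-scale
switch exists because the convention is genuinely ambiguous).

## Per-chromosome summaries

Given a BED6/GTF annotation (read via `rtracklayer`, coordinates stored
1-based inclusive), `chromosome_totals()` sums replicate-mean FPKM of the
detectably expressed genes per chromosome and condition (conservation —
chromosome totals add up to the cohort total — is a tested invariant),
and `deg_positional_map()` lays responsive genes along chromosomes with
their fold-change direction; genes at exactly zero fold change are kept
and flagged neutral rather than silently binned as down.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, with full ground truth:

* **Baseline expression** is a two-component lognormal mixture split at
  1 FPKM (`basal_mixture()`): 28% low (meanlog $\log 0.15$, sdlog 0.6)
  and 72% high (meanlog $\log 20$, sdlog 1.2), reproducing the bimodal
  log-FPKM histogram with an antimode near 1 FPKM and a minority
  low-expression component typical of bulk transcriptomes.
* **Classes**: 5% silent, 28% sub-1-FPKM flat, and the responsive
  remainder split 51 / 36 / 12.5 / 0.1 between increase, decrease,
  stripe and antistripe — the empirically observed division of
  responsive genes. Increase genes are Hill curves with parameters drawn
  from $a \in [0,5]$, $b \in [1,1000]$ (log-uniform),
  $k \in [0.5, 16.7]$, $n \in [0.3, 10]$; decrease genes are mirrored
  Hill curves; stripe/antistripe are Gaussian bumps/dips over dose index
  with an interior peak (on a two-fold dilution grid, index spacing *is*
  log2-dose spacing, so this is the minimal unimodal family over
  log-dose). Responsive draws are rejection-checked so that every
  noiseless planted profile satisfies the classifier's definition of its
  own class — a guarantee the recovery tests rely on.
* **Noise** is multiplicative lognormal with unit median and a stated
  coefficient of variation (an additive-Gaussian switch exists). The
  replicate scatter of FPKM data is multiplicative — replicate log-log
  regressions are tightly linear — but no per-gene dispersion value is
  dictated by that observation, so the default `noise_cv = 0.1` is this
  package's choice of a realistic bulk-RNA-seq replicate CV; tests that
  depend on a noise level state it explicitly.
* **Not emulated**: count-level sequencing noise (negative-binomial
  reads), gene length effects, between-condition library-size drift, and
  correlated noise across genes. Passing recovery tests therefore show
  the pipeline's operations are correct under the model it assumes, not
  that real cohorts will behave as cleanly.

Cohorts are bit-reproducible from the spec (including its seed).

## Numerical and design choices in brief

* Hill evaluation in log space; $f(0) = a$ exactly; no pseudodose.
* KW stage: `alpha = 1` disables the filter (otherwise constant genes
  with $p = 1$ would be dropped by the strict inequality).
* Fold changes of genes silent at both boundary doses are defined as 0.
* Chromosome labels order natural-numerically where numeric.
* Problem sizes in the test suite and acceptance script — 20 noiseless
  genes at 100,000 steps for oracle equivalence, 100 genes at 20,000
  steps for recovery, 1000-gene cohorts for the filter audit and the
  end-to-end run — were chosen to exercise every stage at full fidelity
  while keeping a complete run in the minutes range on one core.

## What the tests assert

Every stage has an independent oracle: brute-force rank arithmetic and
exhaustive permutation enumeration for Kruskal-Wallis; closed-form t
transforms for the correlation filter; an exhaustive grid search for the
MCMC fit; planted ground truth for filters, shapes, clustering and
recovery. The acceptance script (`scripts/acceptance.R`) recomputes the
headline quantities — closed-form error bounds, oracle agreement,
ultrasensitivity call accuracy, filter survivor fractions, shape and
clustering recovery, pipeline invariants, and the delta-Ct transform —
from scratch at a caller-supplied seed.
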