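---
title: "Models and methods: SSR strain typing, Bruvo classification and admixture with inbreeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatpop)
```

This vignette is the package's account of its science: the models it
implements, the numerical choices behind them, what the synthetic-data
generator does and does not emulate, and the design decisions that were
genuinely open.

## Strains as multilocus genotypes

The unit of analysis is the multilocus genotype (MLG): the ordered pair of
allele fragment sizes (bp) at each of 8 SSR loci in a diploid genome. Two
isolates are the same "strain" exactly when all 16 alleles agree. The
default panel (`default_loci()`) consists of 8 polymorphic loci with repeat
units of 2 or 3 bp; the repeat-unit length is what converts a bp difference
into mutation steps.

Design choices at the typing layer:

* **Ploidy is fixed at 2** and phase is never represented; allele pairs are
  stored sorted ascending, homozygotes as a duplicated value. A row whose
  input encodes only one allele at a locus is treated as incomplete, not
  silently as homozygous — homozygosity must be written explicitly as a
  duplicated value.
* **Missing data means whole-isolate exclusion.** The typing protocols this
  package targets re-amplify failed loci and drop the isolate if the
  profile stays incomplete; partial profiles never reach the statistics.
* **Allele binning** (`bin_alleles()`) replaces the interactive binning of
  fragment-analysis software with a deterministic rule: greedy single
  linkage in ascending size order with a configurable tolerance (default
  0.5 bp), each bin reported as the rounded mean of its members. Bins that
  end up closer than the tolerance trigger a warning but are kept distinct.
* **Commercial matching** applies the ±1 bp screening per allele (not per
  locus sum), after sorting each pair; an exact 16/16-allele match is
  required for a strain to be *called* commercial. Both were open questions
  in the source protocol description; the per-allele reading is the
  stricter and simpler one.

## Bruvo distance and the relatedness classification

For alleles $a, b$ with repeat unit $u$, the stepwise-mutation distance is
$d = 1 - 2^{-x}$ with $x = \mathrm{round}(|a-b|/u)$. Each extra repeat unit
halves the remaining distance to 1, so single-step mutations are cheap and
distant alleles saturate. Non-integer step counts (possible at a compound
motif locus or for off-ladder bins) are rounded to the nearest integer,
ties away from zero, keeping the stepwise model well defined. For diploid
genotypes the locus distance is the minimum over the two perfect matchings
of allele pairs of the mean per-pair distance (the standard
minimal-matching convention; both genomes have equal ploidy so the
genome-addition/loss variants for unequal ploidy are not needed). The MLG
distance is the unweighted mean over the 8 loci.

Classification against the commercial panel uses the minimum distance to
any panel strain. The bimodality of that statistic in this study system —
a mode near 0 (derivatives of commercial strains) and a mode far away
(indigenous genotypes) — motivates a fixed threshold of 0.25: strictly
below it an MLG is *commercial-related*, at or above it *unique*. The
boundary value itself classifies as unique ("falling below" is strict).
A second threshold, 0.43, is reporting-only: it marks the distance beyond
which genotypes sit in the far mode. The histogram of minimum distances
(0.05-unit bins) is emitted alongside the classification so the bimodality
can be inspected for any dataset.

The full distance matrix is computed once per run and passed to downstream
consumers (permutation tests, NJ export) rather than recomputed, so all of
them see one consistent matrix.

## Population statistics

Heterozygosity statistics are the classical ones: $H_o$ the fraction of
heterozygous individuals, $H_e = 1 - \sum_i p_i^2$ from allele frequencies
over the $2n$ allele copies (plain gene diversity by default; the
$2n/(2n-1)$ small-sample correction is switchable), and
$F_{IS} = (H_e - H_o)/H_e$, undefined at a monomorphic locus. Population
summaries report the mean ± standard error of each statistic across the 8
loci.

Pairwise $F_{ST}$ uses the Nei-style ratio
$(\bar H_t - \bar H_s)/\bar H_t$, where per locus $H_s$ is the mean of the
two within-population gene diversities and $H_t$ the gene diversity of the
unweighted mean allele frequencies, and the per-locus components are
averaged before the ratio is taken. The estimator behind the originally
used toolkit is not documented precisely; this form is the simplest
consistent choice with the right fixed points (0 for identical populations,
1 for disjointly fixed ones), and the choice is recorded in the run
manifest. Weir–Cockerham is deliberately not the default: the analyses this
package supports compare differentiation between configurations (with and
without commercial genotypes) rather than interpret absolute effect sizes.
Negative estimates are clamped to 0 for reporting with the raw value kept.
Significance comes from shuffling individuals between the two populations
(sizes preserved), $p = (1 + \#\{F_{ST}^{perm} \ge F_{ST}^{obs}\})/(B+1)$
— the add-one rule keeps $p > 0$. Permutations default to 999.

Hardy–Weinberg testing defaults to Monte Carlo re-pairing of the pooled
allele copies, because 8-locus SSR genotype tables are far too sparse for
the asymptotic chi-square; the chi-square variant (df = #genotypes −
#alleles) is available and equals the closed-form df = 1 statistic in the
two-allele case.

All statistics run on clone-censored data (each MLG once per sampling
source) to remove clonal oversampling; censoring is idempotent and an MLG
may legitimately appear in several sources.

## Diversity and hypothesis tests

Rarefied richness $E[S_g]$ standardises MLG counts to a common subsample
size $g$ (computed through vegan's exact binomial-coefficient formula;
defaults 15 for sample points and 56 for whole fermentations are config
values, not constants). The genotype accumulation curve draws random locus
subsets of each size (1000 by default) and counts distinguishable
genotypes, with a 90%-of-total reference level: a plateau above it says the
panel resolves nearly all strains. The Friedman test on rarefied richness
across stages is implemented with within-block average ranks and the tie
correction — base R's `friedman.test` omits the tie correction, which
matters for rank-tied richness values, so the statistic is computed
directly and cross-checked against base R on tie-free tables. Either
rarefaction size can feed the Friedman test; that choice is the caller's.
Welch's t-test (unequal variances, Satterthwaite df) compares relative
abundances; outlier removal is never automatic — exclusions are declared in
the call and echoed in the result, keeping the analysis auditable.

Contingency analyses report adjusted standardized residuals
$ASR_{ij} = (O_{ij}-E_{ij})/\sqrt{E_{ij}(1-r_i/N)(1-c_j/N)}$, and a cell is
flagged when the upper tail of $ASR^2$ under $\chi^2_1$ falls below
$\alpha$ divided by the number of cells (0.05/6 ≈ 0.008 for the 2×3
design).

## Admixture with population inbreeding

Wine yeast populations are strongly inbred, so a clustering model that
assumes Hardy–Weinberg within clusters would be badly misspecified. The
model here gives each of $K$ populations its own allele frequencies
$p_{kl\cdot}$ and inbreeding coefficient $f_k \in [0,1]$; a homozygote
$aa$ assigned to population $k$ has probability
$f_k p_a + (1-f_k) p_a^2$ and a heterozygote $ab$ has
$(1-f_k) \, 2 p_a p_b$. Each individual carries membership proportions
$q_i \sim \mathrm{Dirichlet}(\alpha)$ and a per-locus-genotype origin
$z_{il}$ — the origin is drawn per locus genotype, not per allele copy,
because the inbreeding term couples the two copies.

The sampler augments each homozygous locus-genotype with an
identity-by-descent indicator (the $f_k p_a$ route versus the
$(1-f_k)p_a^2$ route). Conditional on the indicators every update is
conjugate: origins are categorical, memberships and allele frequencies
Dirichlet, and each $f_k$ a Beta draw from the IBD counts. This removes all
proposal tuning that Metropolis-Hastings updates would need and mixes well
on the sparse tables typical of SSR data. The core loop is C++ (Rcpp) and
draws through R's RNG, so `set.seed()` makes chains exactly reproducible.

Numerical choices: allele-frequency prior Dirichlet(1) with a floor of
1e-9 after each draw, so no configuration ever has zero probability
(a heterozygote under $f = 1$ hits the floor rather than $-\infty$);
$\alpha = 1/K$ by default (the hyperprior is not documented for the
original tool; a flat simplex prior over mean membership is the neutral
choice); deviance recorded every 10 sweeps post burn-in. Scaled-down
defaults (20&nbsp;000 sweeps, 5&nbsp;000 burn-in) are the package's working
sizes and recover three well-separated planted populations reliably; the
full-scale settings of large published analyses (10 chains × 1&nbsp;000
&nbsp;000 sweeps) remain available through the same arguments.

$K$ is selected by DIC $= \bar D + p_D$ with
$p_D = \bar D - D(\hat\theta)$ evaluated at the posterior means, averaged
over chains per $K$, argmin reported with the full table. Label switching
*within* a well-separated chain is rare; label alignment *across* chains
uses the greedy procedure below.

### Replicate-run alignment and the H statistic

Runs are aligned to a running consensus by repeatedly matching the
unmatched column pair with the highest similarity (smallest squared
distance), over many random run input orders, keeping the best result. Two
aligned runs have similarity $1 - \|Q - Q'\|_F/\sqrt{2N}$ (the normalized
Frobenius form; the original tool's exact pairwise statistic has several
variants, and the choice is recorded in output metadata); $H$ is the mean
over run pairs. Greedy matching is provably optimal only when runs share
structure: on replicate runs of one clustering — the procedure's actual
domain — it coincides with the exhaustive-permutation optimum, and the
tests verify exactly that regime. On arbitrary unrelated matrices greedy
can be suboptimal, which is why the tests construct replicate-structured
Q matrices (noisy column permutations of a common base) rather than fully
independent ones.

### Ancestry-profile R²

Structure–location association is quantified as
$R^2 = 1 - SS_{within}/SS_{total}$ on the membership matrix, group means
per cluster, with label-permutation significance, pairwise group values,
and leave-one-out diagnostics (drop each group; drop each cluster column
and renormalise rows). Profiles are used as-is (no centering or cluster
weighting — whether the original tool centers first is undocumented; the
unweighted form keeps $R^2 = 0$ exactly when group means coincide, and the
degenerate all-identical-profiles case is defined as 0).

## The synthetic-data generator

`simulate_dataset()` produces data with the structure the analyses assume,
plus full ground truth:

* a panel of 72 mutually distinct diploid commercial genotypes on exact
  repeat ladders (allele = base size + unit × repeat count, repeats 8–28,
  per-locus heterozygosity 0.75);
* commercial-related derivatives: 1–4 loss-of-heterozygosity events per
  genotype, weighted towards 1–2 (most derivatives differ by LOH at one or
  two loci; three or four occur in a minority), plus occasional ±1–2
  repeat-unit stepwise mutations at 0.02 per allele. LOH alone always
  leaves a derivative strictly below the 0.25 threshold (each affected
  locus contributes at most half of an allele distance that is itself
  < 1); stepwise mutations can push rare extreme combinations across it,
  which is why recovery is a ≥95% property rather than an identity;
* three inbred indigenous subpopulations ($f = 0.6$) whose repeat ranges
  are disjoint from the panel's and from each other's, so every indigenous
  MLG is far (> 0.45) from all commercial genotypes — verified by
  rejection sampling, not assumed;
* staged sampling: 4 locations × 2 vintages × 3 replicate fermentations ×
  3 stages × 32 isolates, with location-specific mixture weights over
  strain classes (the winery favours commercial and commercial-related
  strains, the vineyards indigenous ones, each vineyard leaning towards a
  different subpopulation so location carries signal). Each fermentation
  draws its class abundances once from a Dirichlet around its location's
  weights and each stage re-perturbs that shared draw tightly — stages are
  correlated, mirroring the near-zero differentiation between fermentation
  timepoints such studies report. No isolates are emitted for t = 0
  (spontaneous fermentations start without detectable *Saccharomyces*).

What the generator does **not** emulate: fragment-analysis noise beyond an
optional ±0.3 bp jitter mode (used to exercise binning), aneuploidy and
partial profiles, genuinely admixed individuals between indigenous
populations, overlapping allele ranges between indigenous and commercial
pools, and coalescent/Wright–Fisher genealogy. Passing recovery tests on
these data therefore shows the estimators are correct under the model's
own assumptions — clean separation, exact ladders — not that real data of
marginal separation would classify as cleanly; on real data the 0.25
threshold inherits whatever ambiguity the empirical distance distribution
has between its modes.

Sampler validation uses the indigenous populations at 50 individuals each
($f = 0.6$, $K$ scanned over 1–6 at 20&nbsp;000 sweeps): DIC selects
$K = 3$, mean membership in the true cluster exceeds 0.9, and posterior
inbreeding lands within a few hundredths of the generating value. These
problem sizes are the package's validation defaults and run in seconds to
minutes on one core.

## Known limitations

* The Bruvo implementation covers equal-ploidy diploids only.
* $F_{ST}$ is a Nei-style ratio of averaged components; users needing
  variance-decomposition estimators should compute them externally from
  the exported genotypes.
* The admixture sampler does not implement parallel tempering or the
  alternative non-admixture modes of the original inbreeding-clustering
  tool (a selfing-rate-only analysis can be approximated as a degenerate
  configuration but is not a supported mode).
* Split networks are not computed; the NJ tree plus the PHYLIP matrix
  export are the supported route to network visualisation in external
  tools.
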