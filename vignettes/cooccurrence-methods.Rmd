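---
title: "Methods: presence/absence co-occurrence analysis with prevalence-specific nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence/absence co-occurrence analysis with prevalence-specific nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccurj)
library(dplyr)
```

## The problem

Correlation analysis of microbial presence/absence (P/A) data asks, for every
pair of taxa, whether they co-occur across samples more or less often than
chance. P/A information is attractive for shotgun-metagenomic surveys because
detection is far more reliable than abundance estimation. Two metrics dominate
practice: the phi coefficient (Pearson's product-moment correlation applied to
two binary vectors, written $r$ below) and Jaccard's index $J$. They are both
functions of the per-pair $2\times2$ contingency table over $N$ samples
("sites"):

* $a$ — sites where both taxa are present (co-presence),
* $b$, $c$ — sites where exactly one is present (mutual exclusion),
* $d$ — sites where neither is present (co-absence),

with $a+b+c+d = N$. Then

$$r = \frac{ad - bc}{\sqrt{(a+b)(c+d)(a+c)(b+d)}}, \qquad
  J = \frac{a}{a+b+c}.$$

The two can disagree sharply on the same data, and the disagreement is driven
entirely by $d$: $J$ ignores co-absences while $r$ is monotone increasing in
them. In microbiome tables, where most taxa are rare and the median co-absent
fraction per pair is around three quarters, this matters constantly. The
package computes both metrics, tests $J$ against an exact prevalence-specific
null, and provides the diagnostics that show where and why the metrics
disagree.

## Null models for the co-occurrence count

**Standard binomial null.** The classical significance recipe for $J$ models
the co-occurrence count $a$ among the $n = a+b+c$ occupied sites as
$\mathrm{Binomial}(n, 1/3)$. The $1/3$ follows from assuming every taxon has
50% prevalence, so that independent taxa yield equal expected $a$, $b$ and
$c$. `standard_binomial_null()` implements this with the success probability
as exactly $1/3$ by default; because the published form of the model is
usually printed with the rounded constant $0.33$, a `"literal"` mode
reproduces that rounding for replication purposes. The default is $1/3$
because the equal-thirds argument forces it; $0.33$ is display rounding, not
a different model.

The 50%-prevalence assumption fails for essentially every real community.
Under it, two common taxa look spuriously positively associated (they
co-occur often simply because each is nearly everywhere) and two rare taxa
look spuriously negatively associated. `test-acceptance.R` reproduces both
failure modes on independently generated fixed-margin pairs.

**Prevalence-specific hypergeometric null.** Condition instead on the
observed occupancies: species 1 occupies $m$ of $N$ sites, species 2
occupies $k$ sites placed uniformly at random. The co-occurrence count $x$
then follows the hypergeometric law

$$P(X = x) = \frac{\binom{m}{x}\binom{N-m}{k-x}}{\binom{N}{k}},$$

which gives each pair its own null centred on $km/N$. This is the
probabilistic model of species co-occurrence introduced by Veech, and it is
the recommended basis for testing $J$: because $J$ is a strictly monotone
function of $x$ once the margins are fixed, an exact tail test on $x$ is an
exact test on $J$. `hypergeometric_null()` is validated in the test suite
against exhaustive enumeration of all $\binom{N}{k}$ placements for every
margin combination up to $N = 8$, and against a seeded Monte-Carlo
re-implementation of the site-assignment experiment (`simulate_null()`,
100,000 trials by default).

**Tail convention and direction.** `tail_probabilities()` decomposes the
mass into $P(X<x)$, $P(X=x)$, $P(X>x)$ and forms the one-sided tails
including the observed point ($p_{\le}$, $p_{\ge}$) — the standard exact-test
convention; mid-$P$ variants are deliberately not offered. A pair is called
positive when $p_{\ge} \le \alpha$ and negative when $p_{\le} \le \alpha$;
each tail is tested at the per-test level with no doubling, because the
direction of an association is read off from which side of the null the
observation falls. On discrete supports both tails can in principle pass at
once; the smaller tail then wins. Observations outside the support clamp to
probabilities 0/1 rather than erroring so that vectorized pair loops never
branch.

**Significance of $r$.** There is no universally agreed null for the phi
coefficient on P/A data. The default here is the classical large-sample
chi-square test, $N r^2 \sim \chi^2_1$ (two-sided); an exact conditional
test built on the same hypergeometric machinery is available via
`r_test = "exact"`. The choice is recorded in every result. The chi-square
approximation is known to be anti-conservative for sparse tables — rare
taxon pairs with large $d$ can reach nominal significance on one or two
co-occurrences. That behaviour is left intact on purpose: it is part of the
pathology being diagnosed, and it is what produces the rare-by-rare excess
of $r$-only detections in the prevalence grid.

## The all-pairs engine

`analyze_all_pairs()` computes cells, metrics, tails and significance for
all $\binom{T}{2}$ unordered pairs (row order of the input matrix; $i<j$).
Familywise error is controlled by Bonferroni: the per-test level is exactly
`family_alpha / n_pairs`, matching the $0.05/844350$ convention for a
1300-taxon table. The implementation is matrix algebra (`tcrossprod` for all
$a$ counts, vectorized `phyper`/`pbinom`/`pchisq`), so the full
1300-taxon, 844,350-pair screen runs in seconds.

Degenerate pairs — any pair involving a taxon present nowhere or everywhere,
which makes $\phi$ and/or $J$ undefined — are retained in the table, flagged,
and never reported significant. Undefined metric values are `NA` with a
`defined`/`degenerate` flag, never a sentinel number. Retaining them keeps
pair counts auditable: grid totals and concordance denominators always sum
to $\binom{T}{2}$.

Downstream summaries:

* `concordance_summary()` reports the significant-pair overlap with all
  three denominators in use (share of $r$-significant pairs missed by $J$,
  share of $J$-significant pairs missed by $r$, and both/union), plus the
  count of both-significant pairs whose directions agree. Direction
  agreement is always measured, never assumed.
* `prevalence_grid()` bins each pair by its two prevalences (bin width 0.05
  by default), placing the lower prevalence on the row axis so the grid is
  orientation-free. Bins are half-open $[lo, hi)$ with the final bin closed
  at 1.0. The `diff_sig` layer ($J$-significant minus $r$-significant per
  cell) makes the characteristic disagreement pattern visible: positive in
  rare-by-common cells, negative in rare-by-rare cells.
* `rare_pair_fractions()` uses a strict `<` cutoff (default 10%) — a taxon at
  exactly the cutoff is not rare.

Thresholding of raw read counts is strict: a taxon is present only when its
count strictly exceeds `min_reads` (default 100), so both 99 and 100 reads
map to absent at the default. The threshold is configurable down to 0, at
which point any positive count is a presence. Empty samples are retained:
under the contingency framing they are legitimate co-absent sites, and
dropping them would silently change $d$ for every pair.

## The synthetic-data generator

Real microbiome P/A matrices with known ground truth do not exist, so every
statistical property of the package is exercised on synthetic communities
with controlled structure.

* `generate_pair()` draws sites i.i.d. from the bivariate Bernoulli law
  $(p_{11},\, p_1-p_{11},\, p_2-p_{11},\, 1-p_1-p_2+p_{11})$. Association is
  parameterized by the joint probability $p_{11}$ (not an odds ratio)
  because both the independence criterion and the hypergeometric framework
  are stated in joint-probability terms; the Fréchet bounds
  $\max(0, p_1+p_2-1) \le p_{11} \le \min(p_1,p_2)$ are enforced.
* `generate_fixed_margin_pair()` fixes exact occupancies and randomizes site
  identity — the generating experiment of the hypergeometric null itself.
* `generate_community()` draws per-taxon prevalences from a long-tailed
  mixture and places taxa independently, optionally overwriting slots with
  injected associated pairs whose parameters are returned as a truth table.

**Prevalence distribution and calibration.** The mixture is
$0.38\,\mathrm{Beta}(0.4, 25) + 0.62\,\mathrm{Beta}(2, 7.5)$: a heavy spike
of very rare taxa plus a moderate-prevalence bulk. The family and its
parameters are this package's choice; they were calibrated once, by
simulation at 286 sites, against two published shape statistics of a
WGS skin-microbiome table — roughly 74% of pairs having at least one member
below 10% prevalence, and a median per-pair co-absent percentage near 77% —
and then frozen. At the default 1300 taxa × 286 sites the generator realizes
approximately 75% at-least-one-rare pairs, 25% both-rare pairs, and a median
co-absence of 76%; the acceptance suite asserts the bands [0.70, 0.80] and
[70, 84] respectively. A community of i.i.d.-placed taxa reproduces the
*marginal* structure of real data but none of its dependence structure:
no compositionality, no shared environmental responses, no sequencing-depth
variation across samples, no classifier misassignment. Passing tests on
these communities therefore validate calibration and power of the tests
under the stated sampling models — they do not certify behaviour under
real-world confounding.

**Randomness.** Every generator takes one explicit integer seed and derives
its whole stream from it (`withr::with_seed`); no global state is consulted
or modified. Identical seeds give byte-identical matrices.

## Numerical choices

* $\phi$ is computed in floating point with the radicand evaluated as
  $\sqrt{(a+b)(c+d)} \cdot \sqrt{(a+c)(b+d)}$, keeping intermediates well
  inside double range for cells up to $10^6$; a test checks agreement with
  log-space evaluation to $10^{-12}$ relative error.
* Analytic pmfs come from R's `dbinom`/`dhyper`, which are exact to double
  precision; normalization is asserted at $10^{-12}$. Monte-Carlo pmfs are
  exact ratios of trial counts.
* Tiny negative tail masses from floating-point cancellation are clamped to
  $[0, 1]$.
* The exact conditional test for $r$ sums all outcomes with probability at
  most $(1 + 10^{-7})$ times the observed outcome's, the same tie tolerance
  convention as `fisher.test`.

## Problem sizes in the test suite

The statistical checks run at the scale the claims are stated for where that
is cheap (the full 1300 × 286 community for shape statistics; 100,000
Monte-Carlo trials for the null-agreement check) and at reduced replicate
counts where only a qualitative rate is being verified (5,000 replicates for
the misclassification demonstration; 10,000 independent pairs for type-I
calibration; 60 seeded communities of 50 taxa for the power check; a
300-taxon community with 80 injected pairs for the prevalence-grid pattern).
These sizes are the package's own trade-off between statistical resolution
and a test suite that runs in a couple of minutes.

## Known limitations

* The analysis is strictly bivariate. Partial-correlation or conditional
  approaches that remove the influence of third taxa are out of scope.
* The hypergeometric null conditions on observed occupancies; it does not
  model uncertainty in the presence calls themselves (threshold choice,
  classifier error).
* The chi-square default for $r$ is anti-conservative for sparse tables (by
  design, see above); users wanting a calibrated $r$ test should select the
  exact method.
* Abundance-based association measures (Spearman, compositionality-aware
  estimators) are intentionally not provided; the package's scope is
  presence/absence.
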