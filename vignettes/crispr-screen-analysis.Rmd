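---
title: "Differential selection in pooled CRISPR screens: models and choices"
author: "crisprDiffSel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential selection in pooled CRISPR screens: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprDiffSel)
```

# The experiment this package analyses

A pooled CRISPR loss-of-function screen infects a cell population with
a library of single-guide RNAs at low multiplicity, so that each cell
carries one guide disrupting one gene. The guide's 20-nt spacer acts as
a barcode: amplicon sequencing of the integrated cassette, counted per
spacer, measures the relative abundance of each mutant lineage. Two
designs are supported end to end:

* **Time-course fitness screens.** The pool is cultured for weeks;
  samples at Day 0, Day 20 and Day 30 reveal genes whose disruption
  causes progressive depletion (growth disadvantage) or enrichment
  (growth advantage).
* **Chemical modifier screens.** Matched arms are grown with and
  without a compound dosed at a sub-lethal level (e.g. its IC25, from
  the dose-response module); depletion under drug marks sensitizing
  genes, enrichment marks resistance genes.

The supported library layout has two sub-libraries (e.g. SET1/SET2)
with one guide per gene each, plus two kinds of negative controls:
*safe-harbor* guides, which cut at a phenotypically neutral locus and
therefore carry the cutting burden without a fitness phenotype, and
*non-targeting* guides with no genomic match.

# The statistical model

## Counts

For guide $i$ and sample $j$ the read count is modelled as negative
binomial,

$$K_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
  \mu_{ij} = s_j \exp(\beta_{0i} + \beta_{1i} x_j),$$

with $x_j \in \{0, 1\}$ the group indicator of the contrast and
$\log s_j$ an offset. The reported effect size is the log2 fold change
$\mathrm{LFC}_i = \beta_{1i}/\log 2$; significance is a Wald test
$z = \beta_{1i}/\mathrm{SE}(\beta_{1i})$ against the standard normal,
two-sided, BH-adjusted per contrast. Standard errors use the expected
Fisher information (IRLS weights $\mu/(1+\alpha\mu)$), the usual GLM
convention. For balanced groups with equal size factors the estimate
equals the log2 ratio of group mean counts exactly, which is what the
unit tests pin against a brute-force likelihood oracle.

## Size factors anchored on controls

`controlSizeFactors()` computes median-of-ratios size factors
restricted to the safe-harbor controls: for sample $j$,
$s_j = \exp\,\mathrm{median}_i (\log k_{ij} - \overline{\log k_{i\cdot}})$
over control guides $i$ with positive counts in every sample. Anchoring
on controls matters because screens violate the usual
"most features unchanged" assumption — under strong selection most
targeting guides move. Two properties are worth stating precisely:

* size factors depend only on control rows, so arbitrarily strong
  depletion of targeting guides cannot move them (tested);
* size factors are identified only up to a common scale. Multiplying
  one sample's counts by $c$ multiplies its size factor *relative to
  every other sample* by exactly $c$; the absolute values all shift by
  $c^{-1/m}$ because the per-row geometric means absorb part of the
  scaling. Only the ratios enter fold changes, so this is harmless, but
  tests of the invariance must be written in ratio form.

The median is taken on the log scale, which interpolates geometrically
when the number of usable controls is even; this matches the reference
implementation in the wider ecosystem to ~1e-10 (cross-checked in the
suite against DESeq2 where available).

## Dispersion estimation

With 2–3 replicates per group, per-guide maximum-likelihood dispersions
are unusably noisy, so `estimateGuideDispersions()` uses a three-step
scheme: (1) gene-wise ML estimates $\hat\alpha_i$ with group means
profiled out; (2) a mean-dispersion trend
$\alpha_{tr}(\mu) = a_0 + a_1/\mu$ fitted by iterated gamma-family
regression with trimming of extreme ratios (outside $[10^{-4}, 15]$
of the trend); (3) maximum a posteriori re-estimation with a normal
prior on $\log\alpha$ centred at the trend. The prior variance is
$\max(\mathrm{var}(\log\hat\alpha - \log\alpha_{tr}) -
\psi_1(\mathrm{df}/2),\ 0.25)$, where the trigamma term approximates
the sampling variance of a log-dispersion estimate and 0.25 is a floor
that keeps the prior from collapsing; both constants are this package's
own choice. When a guide has no residual degrees of freedom (1-vs-1
contrasts) or the instance is too small to fit a trend (fewer than 10
usable guides), the estimate falls back to a documented prior
dispersion of 0.1, a typical count-level overdispersion for pooled
screens; such contrasts are flagged by the config validator. All-zero
guides are flagged and excluded from testing.

## The empirical null and the calling rule

P-values calibrate the *noise* model but say nothing about whether an
effect size is biologically distinguishable from the background of
neutral cutting. `fitEmpiricalNull()` therefore builds the distribution
of log2 fold changes among the pooled negative controls
(non-targeting + safe-harbor): a Gaussian-kernel KDE with Silverman's
rule-of-thumb bandwidth (`bw.nrd0`, matching the default of the
standard `density()` routine), evaluated on a uniform 512-point grid
spanning $[\min - 3h, \max + 3h]$, integrated trapezoidally to a CDF
and renormalized; the effect sizes at CDF 0.025 and 0.975 are the
empirical cutoffs. These conventions (grid size, span, bandwidth rule)
are fixed and documented so a given dataset reproduces bit-for-bit.

`callGuides()` then requires **both** `padj < 0.05` **and** exceedance
of the null band (`rule = "conjunction"`, the default). The two
criteria could also be read disjunctively — FDR alone deciding
significance, the band only labelling direction — and that behaviour is
available as `rule = "fdr-only"`; conjunction is the default because it
is the conservative reading and it makes the calibrated null band
consequential. By construction about 5% of the control guides
themselves fall outside the band (KDE smoothing allows a small
deviation; the suite asserts 5% ± 2%), so the band is a statement about
effect size, not error rate.

## Genes and phenotypes

`callGenes()` applies the one-of-two rule: a gene is significant if at
least one of its (up to two) guides is. With only two guides there is
no majority to vote; guides significant in opposite directions yield
`ambiguous`, reported rather than dropped. `classifyTimeCourse()`
labels a gene *disadvantage* when significant and
$\mathrm{LFC}_{d30} \le \mathrm{LFC}_{d20} < 0$ (progressive
depletion), *advantage* when significant and
$\mathrm{LFC}_{d30} \ge \mathrm{LFC}_{d20} > 0$. The inequalities are
deliberately non-strict so that an exact tie between timepoints counts
as consistent selection. By default significance is required at both
timepoints (`require_both_sig = TRUE`); the requirement can be relaxed
to either timepoint, since "significant and consistent over time" can
defensibly be read either way. `classifyChemical()` maps depleted to
sensitive and enriched to resistant. `compareConditions()` intersects
two screens' significant gene sets (e.g. 2D vs 3D) and partitions the
overlap by direction concordance; `annotateCalls()` left-joins external
gene-keyed tables (essentiality catalogues, pharmacogenomic
associations), filling unmatched genes with `"No data"` and rejecting
duplicate keys.

# The simulator: what it emulates and what it does not

`simulateScreen()` generates screens with known truth under an explicit
growth model: a mutant with relative fitness $f$ (0 = neutral) grows as
$x(d) = x(0)\,2^{d(1+f)}$ over $d$ population doublings, so after
control-anchored normalization its expected log2 fold change is exactly
$d f$ — an analytic target the recovery tests regress against. The
generative chain per sample is: lognormal initial guide abundance
(log-SD 0.3, emulating cloning unevenness); deterministic selection;
one or more multinomial bottlenecks at `coverage` cells per guide
(default 500×, the usual design target; a 3D dissociation/reassembly
passage is modelled as simply one extra bottleneck); NB read sampling
at `depth` expected reads per guide (default 500) with count-level
dispersion `alpha` (default 0.05).

Default layouts mirror the supported designs: 3 baseline + 2 replicates
per timepoint for time courses, 2 + 2 for chemical arms. Harvest-day
doubling counts for the time course are derived from a 2-day doubling
time (the rate implied by 7 doublings in 14 days in the drug arm):
$d = 10$ at Day 20 and $d = 15$ at Day 30. Effect model defaults put
5% of genes at $f = -0.5$ and 5% at $f = +0.5$, assigned at gene level
so both guides of a gene agree.

What the simulator does **not** model — and hence what green tests do
not establish about real data: guide-specific cutting efficiency and
off-target effects (both guides of a gene are exchangeable here), cell
to cell fitness heterogeneity, 3D-specific biology beyond the extra
bottleneck, PCR jackpotting beyond NB overdispersion, and
drug pharmacokinetics. Recovery results on simulated screens are
statements about the inference machinery, not about any particular
biological system.

# Numerical choices and degenerate inputs

* **IRLS**: vectorized across guides, initialized from pseudocounted
  group means, 50 iterations max, convergence at $10^{-12}$ coefficient
  change; means clamped at $10^{12}$.
* **Zero groups**: a guide with zero counts throughout one group has an
  unbounded MLE; it is refitted with +0.5 on every count and flagged
  `zeroGroup`. Guides all-zero in both groups are excluded and flagged
  `tested = FALSE`; BH adjustment runs over tested guides only, with
  missing p-values propagated and excluded from the test count.
* **Dispersion optimization**: golden-section search on $\log\alpha$
  over $[10^{-8}, 20]$, tolerance $10^{-4}$.
* **Null quantiles**: linear interpolation of the trapezoidal CDF; a
  flat CDF stretch resolves to its first grid point. As the bandwidth
  shrinks with dense controls, the cutoffs converge to the empirical
  2.5%/97.5% sample quantiles (tested).
* **FASTQ quantification**: spacers are matched as substrings at any
  read offset, forward orientation by default (amplicon structures
  differ between labs; substring search is the permissive superset).
  Matching is exact by default; `max_mismatch = 1` scans the Hamming-1
  neighbourhood. A read matching two distinct spacers is discarded as
  ambiguous rather than fractionally assigned, preserving integer
  counts and the conservation identity
  assigned + unassigned = total (tested on every fixture).
* **4PL fitting**: Levenberg–Marquardt with deterministic starts (top
  and bottom from data extremes, IC50 from the dose nearest half-span,
  hill = 1). Fits are unconstrained by default since published
  protocols rarely state whether asymptotes were pinned;
  `constrain = TRUE` fixes top/bottom at 100/0. ICx inversion is
  analytic; the default defines x% inhibition relative to the fitted
  top-bottom span, with `mode = "absolute"` for a literal
  $(100 - x)\%$ viability target — both readings of "x% reduction vs
  control" are defensible, and the span-relative one is
  scale-invariant. Structureless data (e.g. flat viability) produce an
  explicit fit error with diagnostics, never silent parameter garbage.

# Problem sizes in the shipped tests

The suite exercises the full chain at sizes chosen to make the
statistical assertions sharp yet quick: oracle equivalence on ≤10-guide
instances; calibration and dispersion recovery on 150–800-guide
matrices; end-to-end recovery on a 2,000-gene, 200-control screen at
depth 500 with a 2-vs-2 drug-arm layout (regression slope of estimated
vs true $d f$ within [0.9, 1.1], ≥80% directional power at
$|d f| \ge 3.5$, ≤5% neutral-gene false calls); bottleneck-variance
rank tests over 20 replicate simulations; and the dose-response module
on 8–9-point grids spanning 0.4–100 µM. A full run takes about half a
minute on one CPU.

# Known limitations

Only two-group contrasts are supported — no multi-factor designs,
covariates, likelihood-ratio tests or paired analyses. Fold changes are
unshrunk (no effect-size moderation, no independent filtering, no
outlier replacement): the empirical null supplies the effect-size
gating those devices usually provide, but rankings deep in the
low-count tail are correspondingly noisy. Gene calling assumes at most
two guides per gene; richer libraries would want a proper aggregation
test. The annotation join matches exact gene symbols only. The
empirical null assumes negative controls share the technical noise of
targeting guides; if cutting toxicity differs systematically between
safe-harbor sites and gene bodies, the band inherits that bias.
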