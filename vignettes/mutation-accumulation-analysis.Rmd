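---
title: "Analysing mutation-accumulation panels: filters, rates, spectra and genomic context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing mutation-accumulation panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamut)
```

## The experimental design this package serves

A mutation-accumulation (MA) experiment propagates many replicate lines
through repeated single-pair bottlenecks so that new germline mutations fix
nearly neutrally and can simply be counted at the end. The design `mamut`
targets is a two-treatment fly panel — here, lines with programmed meiotic
double-strand breaks (`dsb_plus`) against lines in which meiotic DSB
formation is genetically abolished (`dsb_minus`) — sequenced once after ~30
generations and jointly genotyped. The scientific questions are then: does
the treatment change the rate of point mutations, structural variants or
transposable-element (TE) movement; does it change the mutation spectrum;
and do mutations track genomic covariates (G/C content, crossover
recombination rate, replication timing, chromatin state) differently between
treatments?

The package implements everything between the caller outputs and those
answers: hard filtering with symmetric callable-site accounting, line-unique
variant selection, clustering into events, SV and TE reconciliation, rate
estimation with bootstrap confidence intervals, spectrum statistics, and
negative-binomial regressions on chromatin-state windows. A synthetic
experiment generator with planted ground truth makes every stage testable
without any sequencing data.

## Coordinates and containers

All interval data (BED tracks, windows, masks) are 0-based half-open;
variant positions mirror VCF and stay 1-based. `point_to_interval()` /
`interval_start_to_point()` are the only crossing points — mixed-convention
bugs are the dominant failure mode in this kind of pipeline, so the
conversion is never done ad hoc. The joint callset lives in a
`variant_panel`: one record per (contig, position, alt) after multiallelic
splitting, with the six site annotations (MQ, QD, FS, SOR, MQRankSum,
ReadPosRankSum) and per-line genotype/AD/DP matrices.

## The filter stack and callable sites

`filter_thresholds()` collects every cutoff; all comparisons are inclusive
and rank-sum rules use absolute values:

* variant support: ≥ 10 reads for the variant allele (variant mode only);
* MQ ≥ 50, QD ≥ 2, FS ≤ 60, SOR ≤ 3, |MQRankSum| ≤ 8, |ReadPosRankSum| ≤ 4;
* depth within [0.5, 2] × the line's median chromosome-wide depth
  (applied in both variant and non-variant mode — the same criteria that
  gate variants also gate the denominator);
* point variants within 1 kb (inclusive) of a surviving structural variant
  or of a TE insertion are removed.

A site is *callable* iff it is outside the repeat mask and passes the
non-variant filters in **every** line; per-site mutation rates divide by the
callable total, so the accounting identity
`total = repeat_masked + filter_failed + callable` is asserted on every mask.
Missing annotations fail closed for variant candidacy. For callable-site
evaluation the behaviour is genuinely under-determined (joint callers leave
some annotations undefined at invariant sites), so it sits behind
`strict_callable`, default `TRUE` (missing also fails); flipping it to
`FALSE` treats missing annotations as passing for the denominator only.

Coverage-based aneuploidy screening (`detect_aneuploidy()`) flags a contig
whose mean depth is ≥ 1.4 × the line's autosomal median — between the
euploid expectation of 1.0 and the trisomic 1.5; the threshold is a package
choice (the phenomenon is reported in this literature without one) and is
configurable.

## Events: clustering, zygosity, SVs, TEs

"Two or more variants within 1 kb" is ambiguous between pairwise and chained
readings. `cluster_variants()` uses single linkage on consecutive sorted
positions (gap ≤ 1 kb, inclusive), the only order-independent,
partition-consistent reading; a chain may therefore span more than 1 kb end
to end. The stricter pairwise reading is available via `pairwise = TRUE`.
Chains of one variant are SNV or INDEL events; larger chains are MNV (all
SNVs) or COMPLEX (≥ 1 indel), and each chain counts exactly once for rate
estimation. Zygosity is homozygous/heterozygous when all members agree,
otherwise mixed.

SV records survive when unique to one line, genotyped across their analysis
block (the block partition defaults to the whole panel; the original
blocking was operational, not methodological), supported by ≥ 10 spanning
*or* ≥ 10 split reads, and at the caller's maximum quality score.

TE calls of the same family, contig and type merge across lines by single
linkage at ≤ 50 bp (inclusive) — callers report slightly different
breakpoints for the same insertion. Events carried by exactly one line are
de novo; multi-line events are logged as segregating/recurrent and excluded.
Excisions are merged with the same machinery but are never used in the
proximity exclusion by default (the printed rule names insertions; a flag
includes excisions), and carry the caveat that an apparent excision is
indistinguishable from a deletion spanning the TE.

## Rates, intervals and the test battery

`estimate_rate()` is `sum(counts) / sum(opportunity)` with the opportunity
per line being callable sites × adjusted generations (per-site scope) or
generations (per-genome TE scope). `adjusted_generations` is an input with
default factor 1: the published adjustment lives in supplementary material
not reproduced here, rescales absolute rates only, and cancels from
treatment contrasts. CIs are a seeded percentile bootstrap over lines
(10,000 replicates by default); an exact Poisson (Garwood) interval is
selectable, and zero-event types get a one-sided exact upper bound.

The group difference statistic is `100 × |a − b| / ((a+b)/2)`. This formula
is not stated alongside the published rate tables it mimics; it was inferred
and verified against all seven published rows to the printed two decimals,
and is adopted as the definition here. `tract_fold_excess()` computes the
fold elevation implied if the whole between-group excess were confined to
`n_dsb × tract_length` bp of DSB-repair synthesis per genome per generation
(defaults 24 × 5,000 bp); note the result is sensitive to rounding of the
input rates, so the function reports its inputs rather than asserting any
published value.

`compare_groups()` fronts Welch's t, Wilcoxon rank-sum, Levene
(Brown–Forsythe centring by default, matching `car`), Fisher's exact,
Pearson chi-square, goodness-of-fit with exposure-proportional expectations,
exact binomial, and a permutation test on the absolute difference in
coefficients of variation (label permutation, +1/+1-corrected p). The
Monte-Carlo Poisson dispersion test in `family_activity_tests()` compares
the per-line count of active TE families to a mean-matched Poisson via a
parametric bootstrap of the chi-square statistic, again with the +1/+1
correction, so its p-values are never exactly zero.

## Spectrum statistics

SNVs collapse to the six base-pair-symmetric classes (complementing both
alleles never changes the class — a tested involution). Class proportions
get 95% Wilson score intervals; Ts/Tv gets a seeded event bootstrap. The
G/C-site bias test is binomial against the callable-site G/C composition by
default — the only null under which "more likely at G/C sites" is a
statement about per-site rates — with the null probability recorded in the
result; 0.5 can be passed for a raw-count comparison. Indel deletion bias is
an exact binomial against 0.5, with per-sign lower medians. Genic fractions
are tested against the fraction of *callable* sites inside gene intervals;
the nonsynonymous fraction among coding SNVs is tested against a
configurable selection-free null (default 0.744, from the fly literature).
MNV member SNVs are included in spectrum counts (configurable) even though
events count once for rates.

## Windowed regression

Chromatin-state windows carry overlap-weighted (by bp) projections of the
recombination and replication-timing tracks, callable and G/C counts from
the mask, and `power` = callable sites × number of lines. Windows missing
either covariate or with zero callable sites are excluded and flagged.
`fit_nb()` fits an nbinom2 (variance μ + μ²/θ) log-link regression by
maximum likelihood via glmmTMB, with recombination and G/C divided by their
means (as the field does, aiding convergence) and power as a log offset by
default — the interpretable exposure model; the linear-predictor variant is
a flag, and every fit records which was used. The chromatin-state baseline
is BK, the largest class; the state effect is tested by an LRT dropping all
four non-baseline indicators.

The treatment comparison stacks the window table (two rows per window, each
with its own count and its own power), adds treatment main and interaction
terms, and a per-window random intercept fitted by Laplace approximation.
Two numerical points are deliberate: (1) when the random-intercept variance
sits on the zero boundary, the optimiser may flag "false convergence" and
glmmTMB's `logLik()` returns NA even though the maximised objective is
valid — the package reads the objective directly and accepts the fit when
the fixed-effect score is numerically zero; (2) only genuine optimiser
failure triggers the documented fallback, a fixed-effect per-window paired
model, and the output is labelled with the method used.

## The synthetic experiment and what passing tests mean

`generate_experiment()` builds, deterministically from one seed, every input
the pipeline consumes, with planted truth: event counts are Poisson with
mean rate × callable sites × generations per line (per-genome for TE
events); positions are uniform over callable sites subject to spacing
constraints (> 1 kb from any SV/TE insertion and, with extra slack, from
other events of the same line) so that on clean signal the filter stack is
transparent; zygosity is planted directly (0.55 homozygous on autosomes,
0.70 on the X) rather than simulating 30 generations of sib-mating — the
pipeline only ever sees final-generation genotypes. Depths are negative
binomial around the line median with the allele split binomial, giving the
depth and support filters realistic tails; planted artifacts violate exactly
one named rule each by a documented margin and carry their expected
rejection reason. TE calls are jittered ±20 bp (inside the 50 bp merge
window); a configurable fraction of oversized jitter creates deliberate
merge failures and defaults to zero.

The generator emulates the *statistical* structure of an MA panel, not its
sequence reality: there are no reads, no alignment errors correlated along
the genome, no mapping-induced clustering of artifacts, and reference
composition is a two-state block process. Recovery tests therefore
demonstrate that the pipeline's logic is faithful to its rules and that
estimators are calibrated under the stated model — not that the filters
would remove every real-data artifact class.

Default problem sizes are the study's design (16 + 19 lines, 30
generations) on a ~5.3 Mb five-contig miniature genome; the recovery suites
use 25 seeds at that scale, regression recovery uses 50 seeds at 1,000
windows, and the calibration suites use 200 null simulations per test —
sizes at which the binomial acceptance bands in the tests are meaningful.

## Known limitations

* Consequence labels (nonsynonymous/synonymous) and gene intervals are
  inputs; the package predicts nothing at codon level.
* Non-variant-site evaluations come from site tables or the generator, not
  from gVCF/alignments.
* The percentile bootstrap over lines undercovers slightly when per-line
  counts are very small; the Poisson-exact interval is the conservative
  alternative.
* The Monte-Carlo dispersion test is conservative (true size below nominal)
  when active-family counts are very sparse, because the chi-square
  statistic is then heavily discrete and the +1/+1 correction bites; at
  panel scale (tens of lines, around one event per line and family) it holds
  its nominal size.
* The fold-excess model assumes all excess mutations fall in repair tracts
  and is linear in its three inputs; it is a back-of-envelope consistency
  check, not an estimator.
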