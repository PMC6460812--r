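---
title: "Methods and design of the dmrflux pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the dmrflux pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrflux)
```

# Scope

dmrflux implements the post-alignment computational analysis of a two-group
(filtered air, FA, versus diesel exhaust, DE) developmental-exposure study on
neonatal cardiomyocytes: per-CpG differential methylation from reduced
representation bisulfite sequencing (RRBS) counts, rule-based calling of
differentially methylated regions (DMRs), genome-wide methylation summaries
with a directional-skew test, genomic-context annotation, linkage of DMRs to
differentially expressed genes, and mitochondrial stress-test (Seahorse-style
oxygen consumption) metrics. Read trimming, alignment and the negative
binomial expression model itself are out of scope: the pipeline starts from
Bismark-coverage-style count files and a finished differential-expression
table.

# The per-CpG test

For CpG $i$ and group $g$ the methylation level is the coverage-weighted
proportion

$$\hat p_g = \frac{\sum_s m_{is}}{\sum_s N_{is}} = \frac{M_g}{W_g},$$

over the samples with nonzero coverage (samples with coverage 0 contribute
nothing; no imputation). Counts are modelled as beta-binomial with mean $p$
and overdispersion $\phi \in [0, 1)$, so a sample with coverage $N$ has
variance $N p (1-p) (1 + (N-1)\phi)$; $\phi = 0$ recovers the binomial. The
signed statistic is

$$Z = \frac{\hat p_{DE} - \hat p_{FA}}{\sqrt{V_{FA} + V_{DE}}},
\qquad
V_g = \tilde p (1 - \tilde p) \frac{\sum_s N_{is} (1 + (N_{is}-1)\hat\phi_i)}{W_g^2},$$

with $\tilde p$ the *pooled* proportion across both groups. Two design
choices here were settled empirically during development and deserve
explanation:

* **Pooled rather than unpooled variance.** The unpooled plug-in
  $\hat p_g(1-\hat p_g)$ is noticeably anti-conservative at these coverages
  and sample sizes even when the true dispersion is supplied (null fraction
  of $p < 0.05$ near 0.056 instead of 0.050 at coverage 15, $n = 4 + 4$).
  Evaluating the variance at the pooled proportion — the classical score-test
  standardisation, which reduces to the textbook pooled two-proportion
  $z$-test when $\phi = 0$ — restores calibration. The statistic remains
  signed, with $\mathrm{sign}(Z) = \mathrm{sign}(\hat p_{DE} - \hat p_{FA})$.
* **Dispersion estimation.** $\hat\phi_i$ is a per-CpG method-of-moments
  estimate: within each group,
  $E\big[\sum_s N_s (p_s - \hat p)^2\big] = p(1-p)(A + \phi B)$ with
  $A = n_{>0} - 1$ and $B = (W - n_{>0}) - (\sum N_s^2 - W)/W$, solved for
  $\phi$ pooling the two groups and clamped to $[0, 0.99]$. With four
  samples per group this estimate is very noisy, so it is shrunk 50/50
  toward a genome-wide centre. The centre is the *pooled* method-of-moments
  estimate over all CpGs (total numerator over total denominator), not the
  median of the clamped per-CpG values: the median is biased toward zero at
  this sample size (measured 0.013 against a true 0.02; the pooled estimate
  gave 0.0225), and an underestimated centre makes every downstream p-value
  anti-conservative.

p-values are two-sided against the standard normal and adjusted by
Benjamini–Hochberg (`stats::p.adjust`). No smoothing across neighbouring
CpGs is performed — deliberately simpler than kernel-smoothed bisulfite
testing; the cost is reduced power for isolated low-coverage CpGs.

A CpG is tested only when each group has at least two samples with nonzero
coverage; otherwise its statistic and p-value are missing and it can never
be flagged for region formation. When the pooled proportion is exactly 0 or
1 the variance uses $(M + 0.5)/(W + 1)$ so the statistic stays finite.

Residual limitations: the normal reference ignores the sampling noise of
$\hat\phi$, which leaves a mild anti-conservatism that grows with coverage
(at coverage 30 the null $p<0.05$ fraction sits near 0.053). At the
pipeline's operating point — regions require $p < 10^{-3}$ *and* a 10-point
methylation difference — this has no visible effect on false region calls
(zero observed per 50,000 null CpGs).

# DMR calling

The region stage applies fixed rules rather than model-based segmentation:

1. **Flagging** (`flag_significant`): $p < 0.001$ (strict) and
   $|\hat p_{DE} - \hat p_{FA}| \ge 0.10$ (inclusive).
2. **Candidate formation** (`seed_regions`): maximal chains of flagged CpGs
   in which consecutive flagged CpGs lie $\le$ 100 bp apart; the chain spans
   its first to last flagged CpG and absorbs every unflagged CpG in between.
   The criteria themselves say nothing about how candidates arise, so the
   chain rule reuses the only distance constant the criteria mention (the
   100 bp merge radius) and permits regions to contain non-significant CpGs,
   which the 50%-significant rule presupposes.
3. **Qualification** (`apply_dmr_criteria`): span $\ge 50$ bp (end − start
   + 1, first to last member CpG, unpadded), $\ge 3$ CpGs, and $\ge 50\%$ of
   member CpGs flagged.
4. **Merging** (`merge_dmrs`): qualifying regions on the same chromosome
   whose gap is $\le 100$ bp are merged transitively; statistics (CpG
   counts, AreaStat = sum of member-CpG statistics, mean difference,
   direction) are recomputed over every CpG in the merged span. Merged
   regions are *not* re-checked against the qualification criteria —
   criteria first, merging second, in that order.

The test suite holds this whole chain against an exhaustive oracle that
enumerates every pair of flagged CpGs as potential chain endpoints, verifies
maximality by brute force, applies the criteria, and merges by repeated
pairwise passes until a fixed point — across 200+ randomised fixtures of up
to 30 CpGs.

Genomic context uses the DMR midpoint with precedence promoter > exon >
intron > intergenic. The promoter is the 3,000 bp immediately upstream of a
gene's transcription start site, strand-aware (a figure legend in the source
study says "3000 kb", which would make promoters 3 Mb deep — biologically
implausible and inconsistent with the small promoter fraction shown there,
so it is read as 3,000 bp; the window is configurable). Ties between
overlapping genes resolve by precedence, then alphabetically, for
determinism. No sex-chromosome-specific logic is applied.

# Global summaries

`methylation_histogram` bins per-sample percent methylation
($100\,m/N$, zero-coverage cells skipped) into twenty 5% bins, half-open
$[5b, 5(b+1))$ with the top bin closed at 100 — the labels "0–5%" etc. do
not dictate edge handling, so the convention is fixed here and documented.
Group means and across-sample standard deviations are attached per bin.

`direction_skew_test` is an exact two-sided binomial test of whether
hyper- and hypomethylated loci are equally probable: it sums all outcome
probabilities no greater than the observed outcome's (the minimum-likelihood
two-sided convention, matching `stats::binom.test`). The mass is accumulated
in log space, because at $n \approx 12{,}600$ with a few hundred successes
the p-value underflows doubles by thousands of orders of magnitude; the
exact $\log_{10} p$ rides along as an attribute.

# Flux metrics

From each well's DNA-normalised trace the pipeline takes the last rate of
the baseline phase, the minimum after oligomycin, the maximum after FCCP,
and the minimum after rotenone/antimycin A, and applies:

| metric | formula |
|---|---|
| NMOC | min after rotenone/antimycin A |
| basal respiration | last baseline − NMOC |
| maximal respiration | max after FCCP − NMOC |
| ATP production | last baseline − min after oligomycin |
| spare capacity | maximal − basal |
| coupling efficiency | 100 × ATP / basal |

Values are signed and never clamped (an FCCP response below baseline
legitimately yields negative spare capacity). Normalisation by per-well
µg DNA precedes phase summarisation; the order is mathematically immaterial
for a per-well constant and is fixed for reproducible logs. Phases come from
an explicit column, not from injection timestamps. Replicate wells (3–5 per
biological sample) are averaged unweighted into one record per sample;
sample-level coupling efficiency is recomputed from the averaged ATP and
basal rates (ratio of means — stabler when basal is small) rather than
averaging per-well ratios, switchable via `aggregate_sample(coupling =)`.
Groups are compared metric-by-metric with Welch's two-sample t-test (the
study design has unequal group sizes, 8 vs 7, and there is no reason to
assume equal variances). The minimum after rotenone/antimycin A is taken
per well, not per sample average.

# Expression integration

`de_threshold_filter` keeps genes with $|\log_2 FC| \ge \log_2(1.25)$
(a 25% expression difference) at FDR $\le 0.05$; both boundaries inclusive.
`link_dmrs_to_genes` pairs a DMR with a significant gene when they are
within 1 Mb on the same chromosome — distance measured between closest edges
of the gene's transcript span and the DMR span (configurable to TSS
anchoring), inclusive at exactly 1 Mb, zero for overlap — and, by default,
when the expression change opposes the methylation change, judged by the
sign of the DMR's mean difference (not per-CpG signs). `ddct` implements the
qPCR $2^{-\Delta\Delta CT}$ fold change with 18S normalisation and a Welch
t-test on per-sample $\Delta CT$ values.

# The synthetic-data module

The generators define the conditions under which the pipeline is validated;
they are first-class, tested code.

**Methylomes** (`simulate_methylome`): $n = 4$ methylomes per group. CpG
positions are sorted uniform integers with a minimum gap of 2 bp and a mean
spacing of 30 bp, emulating the CpG-dense MspI fragments RRBS enriches —
dense enough that the bp-based region criteria (50 bp span, 100 bp gaps)
are genuinely exercised. Coverage is $1 + \mathrm{Poisson}(\mu - 1)$ with
$\mu = 15$ by default, inside the 8–25 median coverage band typical of
filtered RRBS data; the shift keeps every cell covered, so the
Bismark-coverage round-trip is exact. Methylated counts are beta-binomial
with baseline 0.5 (the hardest regime for a proportion test — maximal
binomial variance) and $\phi = 0.02$, a modest between-replicate
overdispersion. Planted DMRs add a per-CpG proportion offset for DE
samples; an optional global shift emulates genome-wide hypomethylation.
Proportions are clamped to $[0,1]$ unless clamping is disabled, in which
case out-of-range designs are rejected. What the generator does *not*
emulate: bimodal genome-wide methylation, spatial correlation of
methylation levels, bisulfite conversion failure, alignment artifacts, or
coverage that covaries with methylation. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under its own
assumptions, not performance on real RRBS data.

**Flux plates** (`simulate_ocr_plate`): 8 FA and 7 DE samples, 3–5 wells
each, 3 measurements per phase, defaults FA $(10, 4, 15, 2)$ versus DE
$(8, 4, 11, 2)$ pmol O₂/min/µg across the four phases — every respiration
metric lower in DE, mirroring the reported effect direction. Phase means
are specified on the DNA-normalised scale and multiplied by the well's µg
DNA (uniform on $[0.5, 2]$) to produce raw instrument-scale values, so
normalisation recovers the noise-free truth exactly — the basis of the
round-trip test. Pathological phase orderings of *means* are allowed on
purpose so the signed formulas can be exercised. Fewer than 2 measurements
per phase is rejected (phase extrema would be degenerate).

**DE tables / gene models**: unplanted genes get $N(0, 0.1)$ log-fold
changes and Uniform(0,1) FDRs (so a null table has ~5% of genes below any
FDR cut $\alpha$, by construction); planted rows are inserted verbatim.
Gene models are single-transcript, 1–4 exons, written and read as GFF3 via
rtracklayer.

All generators take an integer seed, are bit-reproducible given it, and
restore the caller's RNG state.

# Numerical and degenerate-input conventions

* Exact ties $\hat p_{DE} = \hat p_{FA}$ give statistic 0 and $p = 1$, and
  are excluded from hyper/hypo counts (reported separately in logs).
* Missing per-CpG statistics inside a region contribute nothing to AreaStat
  and the mean difference but count toward the CpG total.
* An empty matrix filters to an empty matrix; an empty DMR set has an empty
  location composition; neither is an error.
* BED output is 0-based half-open, converted from the 1-based inclusive
  internal model.
* Pipeline configs validate all thresholds and input paths before any stage
  runs; a stage failure removes partial outputs and reports the stage name.

# Problem sizes used in the checks

The bundled tests and the acceptance script run at sizes chosen to make the
statistical assertions sharp while staying quick on a laptop: 20,000-CpG
null methylomes for calibration (3-standard-deviation binomial bands around
$\alpha \in \{0.01, 0.05\}$), 50,000-CpG methylomes with twenty planted
10-CpG regions ($\Delta = -0.3$, coverage 30) for recovery and null
specificity, 220 randomised small fixtures for the region-caller oracle,
600 replicates for the skew-test type-I rate, and full-size (8 + 7 sample)
flux plates.

# Known limitations

* The per-CpG test gains no strength from neighbouring CpGs; single-CpG
  power is lower than smoothed methods at equal coverage.
* Dispersion is per-CpG with global shrinkage; no mean–dispersion trend is
  modelled.
* The candidate-chain rule cannot produce a region whose flagged CpGs are
  farther than the join gap apart, even if the interval would satisfy the
  50% rule; this is intentional and documented above.
* The gene model is single-transcript; promoter and exon definitions ignore
  alternative isoforms.
* Exact binomial skew p-values below ~1e-308 underflow the returned double;
  use the `log10_p` attribute.
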