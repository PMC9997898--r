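---
title: "methdmr: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methdmr: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methdmr` implements a deliberately small, rule-based differential
methylation workflow for two-group WGBS designs with very few
biological replicates (typically *n* = 3 per group). This vignette is
the package's own account of what it computes, which conventions were
genuinely open and how they were fixed, and what the synthetic
benchmark does and does not demonstrate.

## Data model

A sample's methylome is the per-cytosine output of a bisulfite caller:
for each CpG cytosine a chromosome, a 1-based position, a strand and
methylated/unmethylated read counts. Because CpG methylation is
symmetric across the dyad, the two strands' calls at positions *p* and
*p* + 1 measure the same epigenetic state; `destrand()` merges them by
summing counts onto the + strand coordinate. Destranding is on by
default in the pipeline (it roughly doubles per-site coverage, which
matters at 15–30× per strand) and can be disabled for callers that
already report dyads.

`unify()` then applies the *all-samples rule*: a site enters the
analysis matrix only if its coverage is at least `min_cov` in **every**
sample. This is the natural rule for the embryo analysis, where
coverage is limiting and only CpGs "common to all samples" are
comparable, and we apply it uniformly to the sperm analysis as well
rather than introduce imputation; a site that is missing in one
replicate cannot contribute to a 3-vs-3 *t*-test without inventing
data. `min_cov` defaults to 10, the customary coverage floor in
methylKit-style analyses; all benchmark scenarios state it explicitly.

The per-site methylation rate is the plain proportion
methylated/(methylated + unmethylated). All downstream rules operate on
the rate scale, because every threshold in this workflow (20-point
differences, 10/20 % bins) is stated in percentage points of
methylation; no logit or arcsine transform is applied before testing.

## Promoter DMCs

Promoters are the `upstream` = 2000 bp strictly 5′ of each TSS:
`[t − 2000, t − 1]` on +, `[t + 1, t + 2000]` on −, clipped at
position 1. The TSS base itself is excluded — "upstream" is read
literally, and the boundary tests pin this (a site at the inclusive
promoter end belongs; the TSS position does not). Overlapping
promoters are not merged: a CpG inside two promoters is annotated with
both genes but tested once, which prevents double-counting DMCs while
keeping the gene lists intact.

A promoter site is a DMC when a two-sided two-sample *t*-test on the
per-sample rates gives *p* < 0.05 **and**
|p̄_treated − p̄_control| ≥ 0.20, with direction (hyper/hypo) given by
the sign. Three choices deserve comment:

- **Pooled vs Welch.** The default is the pooled-variance (Student)
  test, with Welch available via `var_equal = FALSE`. At *n* = 3 per
  group, the Satterthwaite degrees of freedom of the Welch statistic
  are so noisy that the test is markedly conservative: under a
  matched-variance binomial null at 30× coverage its observed
  *p* < 0.05 rate is ≈ 0.035, while the pooled test sits at ≈ 0.05 as
  a calibrated test should (the acceptance suite measures exactly
  this). In a two-arm design measured with one assay on one tissue the
  equal-variance assumption is reasonable, so the calibrated test is
  the default and Welch is the option.
- **Degenerate sites.** With three replicates, zero-variance sites are
  common (e.g. all reads methylated in all samples). The guards are
  explicit: both groups constant and equal → *p* = 1; both constant
  but different → *p* = 0. The statistic is never NA.
- **No multiple-testing correction by default.** The workflow filters
  on raw *p* < 0.05 combined with a large effect floor; the effect
  filter, not the *p*-value, carries most of the specificity.
  Benjamini–Hochberg adjustment is available (`fdr = TRUE`) for users
  who want it.

## Windowed DMRs

A *qualifying window* is a contiguous run of unified CpGs with
(i) at least `min_cpgs` = 10 members, (ii) genomic span
(last − first + 1) ≤ `max_span` = 300 bp, and (iii) absolute mean of
the signed per-site differences ≥ `diff_threshold` = 0.20. Three
conventions were open and are now pinned by tests:

- "within 300 bp" means span ≤ 300 under 1-based inclusive
  arithmetic: ten CpGs spanning exactly 300 bp qualify, 301 bp do not.
- The 20-point rule applies to the *regional average* of signed
  differences; individual member sites may be below 0.20 (or even of
  opposite sign). An optional strict mode requires all member sites to
  share the region's sign.
- The scanner emits every *maximal* qualifying run — runs not
  contained in a larger qualifying run. Maximality cannot be decided
  greedily because the mean criterion is not monotone under extension;
  the implementation enumerates candidate (start, end) index pairs
  with prefix sums and a span-limited two-pointer bound, then removes
  contained ranges. Its contract is verified against an exhaustive
  O(n²) oracle on random chromosomes.

Windows of the same direction whose genomic spans overlap by ≥ 1 bp
are merged into one reported DMR (connected components), with
statistics recomputed over the union of member sites; opposite
directions never merge, and windows separated by any gap stay
separate. Merging is the package's own reporting convention — the
window definition, which the oracle pins, is the unit of correctness.
A union-preservation test guarantees merging neither gains nor loses
covered bases per direction.

## Peak proximity

Peaks arrive as scored BED intervals and are filtered at
`min_score` ≥ 50, the conventional "significant" cutoff on the
−10·log₁₀(q) score scale used by ChIP peak browsers. A DMR [s, e] is
proximal to a peak if the peak overlaps [s − 1000, e + 1000] by at
least one base: "vicinity (± 1 kb)" is read as a distance bound, not
containment. With `flank = 0` this reduces to plain overlap, and
growing the flank can only add pairs (tested). Nearest-peak distances
are reported from the unflanked DMR.

## Embryo (morula) analysis

On the all-samples matrix the per-site difference
Δ = p̄_treated − p̄_control is binned with strict inequalities:
`hyper20` (Δ > 0.20), `hyper10` (0.10 < Δ ≤ 0.20), `hypo10`
(Δ < −0.10), else `neutral`. The bins are disjoint and exhaustive;
a difference of exactly 0.20 falls to `hyper10`, exactly 0.10 to
`neutral`, matching a strict ">" reading of the plotting convention
the bins come from.

PCA treats samples as observations and sites as variables, on
mean-centred, unscaled rates — rates rather than counts so that
coverage differences between samples do not masquerade as methylation
structure, and unscaled because all variables are already on the
common [0, 1] rate scale. For reproducible tests each axis' sign is
fixed by forcing its largest-magnitude loading positive. With *k*
samples only *k* − 1 axes carry variance; the reported fractions sum
to 1 over those axes.

## The synthetic generator

`simulate_wgbs()` exists so that every claim above is measurable. It
emulates:

- a clustered CpG map: background CpGs at mean spacing 150 bp plus
  dense (25 bp) CpG islands placed in promoters;
- sperm-like baselines — a bimodal mixture, mostly high methylation
  (Beta mean 0.80) with a low component, and largely unmethylated
  promoter islands (mean 0.08, with a 30 % intermediate component so
  hypomethylation effects have room) — or morula-like baselines, a
  unimodal Beta with target grand mean 0.19 at which the recovered
  control-group mean is unbiased;
- hierarchical count noise: per-strand coverage ~ NB(μ = 15,
  size = 15) (so dyad totals are NB(30, 30), overdispersed relative to
  Poisson with < 1 % of sites dropping below 10× in any sample);
  per-sample methylation probability ~ Beta around the group rate with
  variance φ·μ(1 − μ), φ = 0.005 by default — the modest
  between-replicate variability expected of inbred animals on one
  platform; methylated counts ~ Binomial;
- planted truth: DMRs as 12 CpGs placed within exactly 250 bp with a
  ±0.30 rate shift on redrawn baselines that leave the full shift room
  (so every planted region satisfies the window criteria on true
  rates, by construction); one planted DMC per selected promoter at
  ±0.35; high-scoring peaks within 1 kb of 60 % of planted DMRs plus
  background peaks straddling the score cutoff; optionally a uniform
  treated-group shift for sample-separation scenarios.

Effect sizes are additive on the rate scale (clamped), because the
calling thresholds are rate-scale; a logit-shift mode exists. One seed
determines everything, to the byte.

What the generator does **not** emulate: mappability gaps and
repeat-driven coverage holes, bisulfite conversion failure,
strand-biased coverage, spatial correlation of methylation beyond the
planted blocks, and batch structure. Passing the planted-truth
benchmarks therefore demonstrates that the *rules are implemented
correctly and have the expected operating characteristics under the
stated noise model* — not that real sperm or morula data will yield
comparable sensitivity.

## Benchmark problem sizes

The default generator produces ≈ 20,000 unified CpGs over two 1-Mb
chromosomes — large enough that Monte-Carlo checks are tight
(3 standard errors on a 5 % rate is ± 0.47 points at that size) while
the whole test suite and the acceptance script each run in well under
a minute. Oracle-equivalence checks use 50 random 200-site chromosomes
against the exhaustive window enumeration and all-pairs interval
oracles; recovery uses the standard scenario above (50 planted DMRs,
60 planted DMCs) at fixed seeds.

## Known limitations

- The *t*-test on 3-vs-3 proportions is crude by design (it mirrors
  the workflow it implements); beta-binomial regression callers will
  be better powered on real data.
- DMR extraction has no significance test — regions are rule-based,
  and their false-call behaviour is characterised empirically on the
  null generator instead.
- The all-samples rule discards sites aggressively at low coverage;
  at morula-like depth this is the point (comparability), but users
  with more replicates may prefer a per-group coverage rule, which
  this package does not implement.
- Chromosome names are matched by exact string equality;
  `normalize_chrom()` exists precisely so mismatches fail loudly
  rather than silently.
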