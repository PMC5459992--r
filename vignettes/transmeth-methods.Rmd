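---
title: "Methods: scoring addiction-like behaviour and tracking sperm methylation differences across generations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring addiction-like behaviour and tracking sperm methylation differences across generations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transmeth)
```

## Overview

`transmeth` implements a desk-scale pipeline for a classic transgenerational
epigenetics design in the rat cocaine self-administration model:

1. **Behaviour.** Rats acquire intravenous cocaine self-administration under
   fixed-ratio (FR) schedules, then run a progressive-ratio (PR) session.
   Each animal's mean FR5 active pressing and its PR break point are
   standardised within the cohort and summed into a combined drug-seeking
   score; the top 25% are labelled *Addict* and the bottom 40%
   *Non-addict*.
2. **Sperm methylome.** Reduced-representation bisulfite sequencing (RRBS)
   coverage tables from sperm of Saline/Addict/Non-addict F0 sires and
   Addict/Non-addict F1 offspring are filtered, tested per CpG for
   Addict-vs-Non-addict differential methylation within each generation,
   and intersected into direction-consistent *maintained differences*.
3. **Annotation and structure.** Maintained CpGs are annotated to promoters
   (TSS±2,000 bp), exons and introns; enrichment is expressed as odds
   ratios with Wald confidence intervals; global structure is summarised by
   metagene methylation profiles and classical MDS of samples.
4. **Integration.** Genes whose promoters carry maintained differences are
   overlapped with an offspring differential-expression table
   (fold change ≥ 2, *P* < 0.05) and the overlap is scored with an
   upper-tail hypergeometric test.

Because raw animal data are not required, a synthetic-data module generates
operant session logs and RRBS-like count matrices with *planted* effects, so
each stage can be verified against known ground truth.

## Behavioural scoring

The PR requirement for the *i*-th injection is

$$r(i) = \lfloor 5\,e^{0.25 i} - 5 \rfloor,$$

and the **break point** is $r(k)$ for the last injection $k$ the animal
earned. The notation Int(·) in the source literature is read as truncation
(floor); part of the operant literature rounds to nearest instead, so
`pr_requirement(..., rounding = "round")` switches convention.

The **combined score** is $z_{FR5} + z_{BP}$, with each metric standardised
as $(x - \bar x)/s$. We default to the sample standard deviation
($n-1$ denominator); the population version ($n$) is a documented switch
(`sd_type`) because the printed description of the score is ambiguous on
this point. The two differ by a factor $\sqrt{(n-1)/n}$ applied to both
metrics, so the classifier's ranking — and therefore the labels — are
identical under either convention.

**Classification** labels exactly $\lfloor 0.25\,n \rfloor$ animals Addict
and $\lfloor 0.40\,n \rfloor$ Non-addict. Whether the original percentile
cuts interpolated quantiles or how they treated ties is unstated; we adopt
floor counts with a deterministic tie-break by (score, animal id), which
makes classification reproducible for any input order.

Break points between groups are compared with a Mann–Whitney rank-sum test:
exact enumeration of all $\binom{n}{n_a}$ rank assignments when
$n_a + n_b \le 12$, otherwise a normal approximation with tie and
continuity corrections.

## The differential methylation test

CpGs are first filtered to those detected (coverage ≥ 5×) in strictly more
than 6 of the 16 samples. Within a generation, methylated/unmethylated
counts are **pooled across samples per phenotype** and each CpG is tested
with a two-sided Fisher exact test; Benjamini–Hochberg correction is
applied across tested sites and significance is called at FDR ≤ 0.05
(a raw-p mode exists behind `use_raw_p`, since the source's Methods and
figure legends disagree on the threshold's definition). *Maintained
differences* are CpGs significant in both generations with the same sign
of the Addict−Non-addict difference; direction consistency is implied
rather than stated in the source material, and we require it.

Pooling counts is a deliberate simplification relative to per-sample
modelling (e.g. beta-binomial regression or DMR smoothing): it is exact,
fast, and verifiable against an independent hypergeometric enumeration
oracle to 10⁻¹². Its cost is anticonservativeness when samples are
overdispersed relative to binomial — exactly the situation the simulator's
beta-binomial model creates (see *Known limitations*). `dmc_test()` emits
a caveat when the between-sample variance of levels exceeds three times
its binomial expectation.

## Element annotation and enrichment

Promoters are the closed interval TSS ± 2,000 bp around the strand-aware
TSS (for a − strand gene the TSS is the higher coordinate). Precedence is
promoter > exon > intron > intergenic; a CpG inside several promoter
windows is assigned to the nearest TSS. Coordinates are 0-based half-open
internally; bismark-style coverage files are read and written 1-based by
default (`coord_base` switches the dialect — note that real bismark `.cov`
exports are 1-based even though BED-like in shape), and BED outputs are
0-based half-open.

Hypomethylated CpGs are those whose **maximum** per-sample methylation
fraction across covered samples is ≤ 0.3 (inclusive). Enrichment of a site
class within the maintained set is an odds ratio $ad/bc$ with the
Haldane–Anscombe +0.5 correction when any cell is zero, a Wald 95% CI on
the log scale, and a Fisher exact p.

## Metagene profile and MDS

The metagene axis is a fixed 2,000 bp upstream flank, the gene body
rescaled to [0, 1], and a 2,000 bp downstream flank, each cut into 20 bins
by default. Site levels are pooled per sample group; bins without sites are
reported as missing (NA), never zero; − strand genes are reversed. Sample
structure is summarised by classical (Torgerson) MDS on Euclidean distances
between per-sample methylation-level vectors, computed on complete-case
sites by default (mean imputation behind a flag); each dimension's sign is
fixed so its first nonzero coordinate is positive.

## The synthetic-data generators

### Behaviour

Each of `n_animals` (default 134, the full F0 cocaine cohort size) carries
a latent motivation $m_i \sim N(0, 0.3)$. Sessions follow the training
plan FR1 × 5, FR3 × 2, FR5 × 5, then one PR session. FR5 presses are
negative binomial with mean $200\,e^{m_i}$ and size 8 (about 40 injections
in a 4 h session, with realistic session-to-session spread); FR1/FR3 means
are scaled by ratio so injection counts stay comparable during
acquisition. The PR session walks the requirement ladder until the next
requirement exceeds the animal's press capacity $120\,e^{m_i}$; the logged
break point is the last requirement met. The >1 h-per-requirement stopping
rule of real PR sessions lives in this capacity mechanism; the scorer
trusts the logged injection count.

### Methylome

Per CpG, a baseline methylation probability is drawn from the bimodal
mixture $0.6\,\mathrm{Beta}(0.5, 10) + 0.4\,\mathrm{Beta}(10, 0.5)$ —
RRBS methylation is empirically bimodal. Coverage is negative binomial
(mean 30, size 5; RRBS-typical depth) and methylated counts are
beta-binomial with intra-sample correlation 0.05 (biological replicate
overdispersion). On the logit scale the group structure is:

* **Exposure shift**: −0.3 logits at every site for cocaine-exposed F0
  samples (Addict-F0, Non-addict-F0), emulating the moderate global
  demethylation of exposed sires relative to Saline F0. F1 samples receive
  no exposure shift.
* **Generational drift**: a per-site $N(0, 0.3)$ offset shared by all F1
  samples. Sperm methylomes of consecutive generations differ globally in
  ordination even without treatment, and the observed study ordination
  separates generation as a major axis; a mean-zero site-specific drift of
  the same order as the exposure shift reproduces that geometry without
  changing any Addict-vs-Non-addict contrast (it cancels within F1).
* **Planted effects**: `n_planted_dmcs` (default 200 of 10,000) CpGs get a
  ±1.5 logit Addict shift (sign per site with probability 0.5, since both
  directions occur in real data); a `maintenance_fraction` (default 0.8)
  of them keep the shift in Addict-F1. Effect size and count are
  placeholders for parameter-recovery testing — the real study never
  reports effect magnitudes.

Group sizes default to 4 + 3 + 3 + 3 + 3 = 16 samples (3–4 per group).
When a gene model is supplied, 35% of sites are placed inside promoter
windows and 80% of planted sites are drawn from them, mirroring the
promoter concentration of maintained differences.

All generators consume named substreams of one master seed
(`substream_seed`), so enlarging the methylome never perturbs behaviour
draws, and every run is bit-reproducible.

### What the simulator does **not** emulate

Raw bisulfite reads, conversion failure, PCR duplicates, chromosome
structure beyond one synthetic chromosome, litter/sire pedigree, CpG
clustering/comethylation, and coverage biases of MspI digestion. Passing
tests therefore demonstrate correctness of the computations and
recoverability of planted structure under this generative model — not that
the pipeline would reproduce the original study's counts from real data,
which came from a different (smoothing-based) regional test at much larger
site numbers.

## Problem sizes and numerical choices

Package tests and the acceptance script run the full design at 10,000 CpGs
× 16 samples and 134 animals, with 10–20 seed replicates for
property-style checks — sizes chosen so the complete suite runs in about a
minute on a laptop while keeping every stage at its study-like shape.
Degenerate inputs are handled explicitly: zero-variance cohorts and
all-zero tables raise errors naming the offending metric; PR sessions with
zero injections get break point 0 plus a warning flag; CpGs with zero
pooled coverage in a phenotype are excluded and logged; never-covered
sites yield NA hypomethylation flags and are dropped from enrichment
denominators; ties in classification and annotation are broken
deterministically (score then id; nearest TSS).

## Known limitations

* **Power at study scale.** With 3–4 samples per group at ~30× coverage,
  a 1.5-logit shift at a bimodal-extreme baseline CpG moves the absolute
  methylation fraction very little; joint F0-and-F1 detection then squares
  the modest per-generation power. Under the default generator the
  maintained-difference recovery is accordingly low (median sensitivity
  ≈ 0.07 across seeds) — an honest property of this design at desk scale,
  not a target the defaults were tuned to.
* **Overdispersion vs pooling.** The pooled Fisher test assumes binomial
  sampling within phenotype; with beta-binomial replicates
  (ρ = 0.05) it flags ≈ 1% of null sites at FDR ≤ 0.05, so an occasional
  false maintained site (~1 per 10,000 null CpGs) is expected. The unit
  suite verifies the test is calibrated when ρ = 0 (zero null
  discoveries); real analyses with visible replicate heterogeneity should
  heed the overdispersion caveat and treat borderline q-values
  sceptically.
* The MDS `dims` are unweighted principal coordinates; negative
  eigenvalues (non-Euclidean inputs cannot arise here) are not handled
  specially.

## Reproducing a full run

```{r, eval = FALSE}
cfg <- run_config(seed = 1)
report <- run_pipeline(cfg, out_dir = "transmeth-run")
report          # stage counts, recovery metrics, enrichment, overlap
```

The written bundle (session logs, cohort scores, per-sample coverage
files, DMC tables, maintained-site BED, metagene profile, MDS coordinates,
DE table, summary JSON) re-parses with the package's own readers, and an
identical config + seed reproduces it byte-for-byte.
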