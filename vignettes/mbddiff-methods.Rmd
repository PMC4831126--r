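---
title: "Methods: differential methylation from methyl-capture sequencing"
author: "mbddiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation from methyl-capture sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbddiff)
```

## The problem

MBD-seq enriches methylated genomic fragments with a methyl-CpG binding
domain protein and sequences them; local read density then proxies DNA
methylation.  In a rare-disease setting -- e.g. transient neonatal diabetes
with ZFP57 loss, where maintenance of imprinted methylation fails at
multiple loci -- each patient must be compared *individually* to a small
control group, because the number and identity of affected loci differ
between patients.  `mbddiff` implements that design end to end: region
definition from aligned capture reads, a one-case-versus-controls
negative-binomial exact test, shared-region analysis across patients, and
annotation of the resulting regions (ZFP57 binding motif TGCCGC content,
allele-specific-methylation support, CpG islands, transcript context),
plus an independent bisulfite-amplicon validation arm.

Because patient sequencing data of this kind is not freely redistributable,
the package ships a synthetic-data generator that reproduces the
*statistical structure* the analysis assumes, together with full ground
truth, so every stage can be tested for calibration and parameter
recovery.

## Region definition

**Read filtering.** Reads with mapping quality below 37 are removed;
among the remainder, one read is kept per (sample, contig, 5' position,
strand) -- the standard single-end duplicate criterion.  The 5' position
of a minus-strand read is its right end.

**Region calling.** Each read is extended to the capture fragment length
(default 250 bp, matching a 250 bp sonication target sequenced at 36 bp)
from its 5' end along its strand.  The genome is tiled into 250 bp
windows; a window is significant when the Poisson upper tail
$P(X \ge \mathrm{obs})$ under $\lambda = \max(\lambda_{\rm genome},
\lambda_{\rm 10kb})$ is below $10^{-8}$.  Both rates count fragments
overlapping a window, scaled by the effective window footprint
(fragment + window - 1).  Runs of adjacent significant windows join into
maximal regions.  This is a deliberately simplified capture-peak caller:
the contract is Poisson significance at $p < 10^{-8}$ with a local 10 kb
background, without a shifting model or control-swap FDR.  A practical
consequence worth knowing: the genome-wide rate includes reads inside
regions, so on a *dense* toy genome (region occupancy well above ~10%)
weakly captured regions can fall under the inflated background.  Real
methylomes are sparse; the simulator defaults keep occupancy below 10%.

**Merging.** Region sets called per sample are merged across samples:
two regions merge when their overlap exceeds 50% of the *shorter*
region's length (strict inequality), merged regions take the union span,
and merging repeats to a fixpoint (single linkage over connected
components).  Basing the rule on the shorter region makes
containment-like cases merge and the operation symmetric; the fixpoint
makes it idempotent and order-invariant.  Exactly 50% overlap does not
merge.

**Counting and the RPM floor.** For every merged region and sample, the
number of non-redundant filtered reads whose extended fragment overlaps
the region by at least one base is counted; a fragment spanning two
regions counts in both (regions are scored independently).  Library size
is the sample's total filtered read count.  A region is retained iff its
reads-per-million reaches 20 (inclusive) in at least one sample.

## Differential testing

**Normalization.** TMM-style scaling factors: the trimmed mean (30% of
log-ratios, 5% of abundances, symmetric tails) of log2 relative
abundances against the largest library, centred to geometric mean 1.
Effective library size = raw size x factor.

**Dispersion.** A common negative-binomial dispersion
($\mathrm{Var} = \mu + \phi\mu^2$) is estimated from the *controls only*
by per-region method of moments, $\phi_i = \max\{0, (s^2-\bar m)/\bar
m^2\}$ on counts scaled to a common effective size, summarized as the
median over regions with mean at least 10 and floored at $10^{-4}$.
Patient columns are excluded because they carry true effects, and a
single-case group admits no within-group estimate.

**Exact test.** Counts are scaled to integer pseudo-counts at the mean
effective library size (simple proportional scaling).  Conditional on
the total $T$ of the case pseudo-count and the summed control
pseudo-count, the case count is distributed as one
$\mathrm{NB}(\mu, \phi)$ given the sum with $n$ controls, with
$\mu = T/(n+1)$; the two-sided p-value adds up the probabilities of all
splits no more likely than the observed one.  With $\phi = 0$ this is
the conditional binomial (Poisson) test.  One subtlety: for one case
versus $n > 1$ controls with $\phi > 0$ the conditional mode sits
slightly *off* the proportional split (negative-binomial skewness), so a
perfectly balanced observation has a large p-value but not exactly 1;
the package's tests pin this against an independent convolution oracle
and against edgeR's small-p exact test, which agrees to numerical
precision.  Fold changes are $\log_2\{(y_p + 0.5)/(\bar y_c + 0.5)\}$;
the +0.5 shrinkage avoids infinities at total loss.

**Multiplicity and calling.** Benjamini-Hochberg adjustment per patient
(via `stats::p.adjust`); a region is aberrant when the adjusted p-value
is at or below 0.05 -- the threshold is *inclusive* -- with direction
from the sign of the fold change.  Consistent with the method's design,
total losses of methylation are called with essentially full power at
realistic depth, while 50% (partial) losses frequently do not reach
adjusted significance; the fold-change estimate still centres near -1.

## Shared regions

All patients are tested on one merged region universe, so sharing is
defined by region *identity*, not positional re-intersection, and is
stratified by direction (a hypo call and a hyper call at the same region
never pool).  `venn_counts()` partitions (region, direction) calls by the
exact patient subset calling them -- cells sum to the number of distinct
calls -- and `shared_at_least()` filters on the number of affected
patients.

## Annotation

* **Motif content**: exact occurrences of TGCCGC, by default on both
  strands (forward + the reverse-complement GCGGCA), since the
  zinc-finger recognizes a methylated duplex; a flag restricts counting
  to the forward strand.  `fraction_at_least(counts, 2)` gives the
  "two or more copies" percentage; full precision is kept, display
  rounds to whole percent.
* **AMR support**: each allele-specific-methylation dataset contributes
  at most 1 to a region's score (any >= 1 bp overlap); the headline
  fraction counts scores *strictly above* 5 datasets.
* **CpG islands**: Gardiner-Garden style -- 200 bp windows with GC >= 0.50
  and observed/expected CpG >= 0.60
  ($O/E = n_{CG} \cdot L / (n_C n_G)$), merged into maximal islands.
* **Transcript context**: distances are measured from the region centre
  to the nearest transcript 5' end (strand-aware); "TSS-proximal" is
  inclusive at 1 kb, so "more than 1 kb away" is strict.

## Bisulfite validation arm

Amplicon reads carry an inline sample index.  The printed index set is a
table of 6-mers; the accompanying text describes 5-base indexes.  The
nine indexes are in fact pairwise distinct already at five bases, so
either length demultiplexes them; the package defaults to the full
6-mer and refuses to run if the chosen prefix length makes the table
ambiguous.

Alignment is ungapped and conversion-aware: a read is scored at every
offset against the amplicon under a forward model (reference C may read
T freely) and a reverse model (the reverse complement of the read is
scored with reference G free to read A); the fewest-mismatch placement
wins (forward, then smaller offset, on ties) and is rejected above a 10%
mismatch fraction.  Gapped alignment is deliberately omitted: amplicons
are short PCR products where indels are rare, and rejected-read counts
surface violations.  Methylation calls are read at each covered CpG
(C/T on the forward strand; the paired G/A one base downstream on the
reverse strand, assuming symmetric CpG methylation).

Per CpG the methylated *fraction* $m/(m+u)$ is used rather than the
odds $m/u$: fractions are bounded and averageable, which is what an
amplicon-level mean requires.  The per-amplicon value is the unweighted
mean over CpGs with coverage >= 10.  Capture-versus-bisulfite agreement
is summarized as the Pearson correlation of paired log2 ratios against
the control-group mean, with a pseudo-value of 0.01 on both scales to
keep total losses finite.

## The synthetic-data generator

`sim_config()` fixes the study conditions: a 12-sample cohort (4
patients, 3 heterozygotes, 5 controls); a toy genome whose background is
actively CpG-depleted while regions are GC-rich with ordinary CpG
content, so island detection is testable; designated DMRs receiving a
Poisson number of exact TGCCGC insertions at recorded offsets (region
sequences are scrubbed of chance motif hits first, so recorded counts
equal a direct scan); capture counts
$\mathrm{NB}(\mathrm{depth} \cdot w_i/\sum w \cdot m_{is},\ \phi)$ with
gamma(8, 8) baseline weights, multiplier 1 wherever no effect is
declared; 30% of depth added as uniform background reads; 5% of reads
given sub-37 mapping quality and 5% duplicated, so filtering has work to
do.  The default effect table plants three total losses (multiplier 0)
in all four patients, partial losses (0.5) in patient subsets, two gains
and one mild heterozygote effect.  Dispersion defaults to
$\phi = 0.1$ -- visibly overdispersed yet detectable at desk depth.

Everything is seed-deterministic to the byte.  What the generator does
*not* emulate: sequencing-error models beyond uniform substitution,
paired-end reads, fragment-length variation, GC bias in capture
efficiency, real genome coordinates or repeat structure.  Passing tests
therefore demonstrate the statistical machinery under the model's own
assumptions, not robustness to artefacts of real libraries.

## Problem sizes and runtime choices

The package's standard experiments, chosen once as desk-scale analogues
and used by the test suite and the acceptance script:

* null calibration: 2000 regions, 5 controls, $\phi = 0.1$, control
  mean 100;
* power for total loss: control mean 1000 (depth $10^6$ at region
  weight fraction $10^{-3}$), a 100-region BH family, 100 seeds;
* end-to-end recovery: 2 x 200 kb contigs, 60 regions, depth
  $2\times10^4$ per sample, 100 seeds (about 2.5 s per seed);
* bisulfite arm: 8 amplicons x 9 samples, 200 reads per amplicon,
  baseline methylation 0.8.

## A worked example

```{r example}
cfg <- sim_config(seed = 7, n_contigs = 2, contig_length = 2e5,
                  n_regions = 60, depth_per_sample = 2e4)
sim <- simulate_genome(cfg)
reads <- simulate_capture_reads(sim)
an <- mbd_analyze(reads, sim$contig_lengths, cfg$cohort)
an
shared_at_least(an$shared, 4)$hypo
```

The three regions recovered in all four patients are, by construction,
the three engineered total-loss DMRs; partially hypomethylated regions
appear in the per-patient tables with negative fold changes but often
adjusted p-values above 0.05, mirroring the method's real sensitivity
profile.

## Known limitations

* The peak caller is a declared simplification (no model shift, no
  control track); its contract is windowed Poisson significance only.
* Library equalization uses proportional pseudo-counts, not a quantile
  adjustment; with very unequal libraries the conditional test is
  approximate.
* The common dispersion is a moment median from a handful of controls;
  no empirical-Bayes shrinkage toward a trend.
* Fragment assignment double-counts fragments spanning two regions;
  region scores are therefore not additive across adjacent regions.
* On toy genomes with region occupancy well above ~10% the genome-wide
  background rate is inflated and weak regions may be missed.
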