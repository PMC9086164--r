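---
title: "Quantifying and testing A-to-I RNA editing with editscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and testing A-to-I RNA editing with editscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscape)
```

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA; sequencers
read inosine as guanosine, so editing events surface in RNA-seq alignments as
A-to-G mismatches. Given per-site counts of A-supporting and G-supporting
reads across samples, one wants to (i) keep only credible editing sites,
(ii) say where each site falls in the transcript architecture and what an
edit would do to a codon, (iii) characterize the nucleotide context ADAR
prefers, (iv) test whether editing levels differ between two groups of
samples (here: a case/control brain-tissue design with 12 samples per
group), and (v) ask whether a site's editing level tracks the expression of
its host gene across samples (a cis-regulatory signature).

`editscape` implements that pipeline downstream of alignment and variant
calling: its inputs are base counts, a reference FASTA, a GTF subset, a
catalogue of known editing sites, sample metadata, and a gene-count table.
Everything upstream (alignment, deduplication, SNV calling) is out of scope
by design — those steps are served well by existing tools and contribute
nothing to the statistical questions here.

## Editing level and the high-confidence filter

The editing level of a site in a sample is

$$\varphi = \frac{n_G}{n_A + n_G},$$

the fraction of reads supporting the edited base among reads supporting
either allele, after strand adjustment (a site in a '-'-strand gene appears
as T-to-C on the genomic forward strand and is stored canonically as A-to-G
with strand '-'). When $n_A + n_G$ falls below `min_coverage` (default 10
reads) the level is *missing*, not zero: an undercovered cell can neither
satisfy nor fail a threshold. The filter retains a site iff

* its level is at least `min_level` (default 1%) in at least `min_samples`
  (default 2) samples, **or**
* it matches the known-site catalogue on (chrom, pos, strand).

Both branches are logged per site (`filter_high_confidence()`), and the
filter is provably monotone: raising either threshold can only shrink the
retained set, adding catalogue entries can only grow it.

Strand policy for canonicalization: the strand of an overlapping gene wins;
unannotated positions fall back to the substitution-implied strand; an
A-to-G call antisense to its gene is rejected by default
(`allow_antisense = TRUE` keeps it). The full 12-substitution-by-strand
policy is pinned in a test.

### Per-group accounting

A site is "detected in group g" when at least `detect_min_samples` (default
1) samples of g have a defined level at or above `min_level`. The spec of
this rule is genuinely open — published site totals rarely state it — so it
is a parameter, not a constant. Retained sites are partitioned into
case-exclusive / control-exclusive / shared / neither; the fourth bucket
exists because a site retained purely through the catalogue branch can be
detected in no group at all. The four counts always sum exactly to the
retained total; in typical runs `neither` is zero or tiny.

## Consequence annotation

A minimal annotator replaces external tools so that results do not depend
on a database version. For each site and each overlapping transcript:
exonic positions of coding transcripts split into 5'UTR / CDS / 3'UTR by
transcript coordinates; within the CDS the edited codon is translated with
the standard genetic code and called synonymous, missense, or stop_lost;
intronic and non-coding cases get their own categories; sites outside every
transcript are intergenic. One call per site survives, by a fixed severity
order (stop_lost > missense > synonymous > 5'UTR > 3'UTR > non-coding exon >
intron > non-coding intron > intergenic). Two consequences of the code
table worth noting: under A-to-G editing only TAG (position 2) and TGA
(position 3) can lose a stop, both becoming TGG (Trp); and no stop can be
gained. Splice-region categories are deliberately not emitted; sites near
exon boundaries classify by containment. Category calls are invariant under
reverse-complementing the genome and flipping all coordinates — a property
test, and a useful guard on the coordinate arithmetic.

## Sequence context

`extract_contexts()` collects the strand-adjusted ±6 bp window around each
site (reverse-complemented for '-' sites, so "upstream" is always 5' on the
edited strand; position 0 is by construction 100% A).
`position_enrichment()` makes the qualitative notion of "preference"
operational: for every flank position and base it builds the 2×2 table of
observed counts against the reference genome's overall base composition and
computes a two-sided Fisher exact test plus the sample odds ratio, with BH
adjustment across the 48 position×base cells. The background is the plain
mononucleotide composition of the same reference — no dinucleotide
correction — because the aim is direction (ADAR's depleted G at −1,
preferred G at +1), not a calibrated motif energy.

## Differential editing

Per retained site, defined levels are compared between groups with the
Kruskal–Wallis test (average ranks, tie correction, chi-square upper tail
with $k-1$ df). Sites with fewer than `min_per_group` (default 3) defined
values in either group are skipped with a logged reason — the chi-square
approximation is not trustworthy below that. The default significance rule
is raw $p < \alpha$ with $\alpha = 0.05$, matching the reporting convention
of the study design this package targets; BH-adjusted values are always
computed alongside, and `use_fdr = TRUE` switches the rule, because raw-p
site lists at thousands of sites carry an expected ~5% false-positive rate
(the null-calibration test demonstrates exactly that). Direction is the
sign of (case mean − control mean) among significant sites.

For the sample-level overview, PCA runs on the significant sites: sites
with >50% missing cells are dropped, remaining missing cells are imputed
with the site mean, sites are centered, and the samples are projected. The
loading of largest magnitude in each component is forced positive, making
scores reproducible. Percent variance per component sums to 100.

## Cis-regulation

Expression is normalized to TPM (per sample: count/length, rescaled to sum
to $10^6$), with effective gene length the exon-length sum of the gene's
longest transcript. Editing–expression association per (site, host gene)
pair is Spearman's rank correlation with the two-sided t-approximation on
$n-2$ df; TPM is not log-transformed since ranks are invariant to monotone
transforms. Host genes come from the consequence annotation, so intergenic
sites are skipped with a reason, as are genes with zero expression
variance. Sites with $p$ below `p_cutoff` (default 0.05) are cis
candidates. `run_all()` scans the significant differential sites by default
(mirroring how such studies restrict the question); `cis_sites = "genic"`
scans every retained genic site instead — the recovery analyses use this
mode because the generator plants cis couplings independently of group
effects.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the two-group
postmortem-brain RNA-seq design the pipeline targets and carries full
machine-readable truth.

* **Genome and genes.** Random uniform-composition chromosomes (default
  2 × 1 Mb) host non-overlapping single-transcript gene models (default
  300; 15% non-coding), each with 2–5 exons; coding genes carry UTRs and a
  CDS whose start/stop codons are physically written into the reference, so
  sequence and annotation agree by construction. CDS features include the
  stop codon.
* **Sites.** Default 3000 positions with strand-adjusted reference base A,
  ≥7 bp apart, clear of start/stop codons, targeted into transcribed
  regions 90% of the time (editing is observed in RNA reads, so sites should
  mostly be genic; the remainder exercises the intergenic path). The −1/+1
  neighbors are rewritten so G occurs with the configured probabilities
  (defaults 0.05 at −1 and 0.6 at +1 against a 0.25 background — the
  depleted-upstream / preferred-downstream ADAR signature).
* **Levels and counts.** Baseline mean levels are Beta(1.5, 6) (mean 0.2,
  mostly low editing, as in brain tissue). Per sample-site cell, coverage is
  negative binomial (mean 50, size 10), the sample-level
  $\varphi$ is Beta-distributed around the group mean with concentration 30,
  and edited reads are Binomial(coverage, $\varphi$) — the standard
  overdispersed model for allele counts. The study provides no coverage or
  dispersion figures, so these are generic desk-scale choices, flagged as
  such.
* **Planted structure.** 40 differential sites get the case-group mean
  shifted by −0.15 (clamped to [0, 1]; negative to mirror the predominance
  of down-editing in the case group of the motivating design). 6 cis sites —
  disjoint from the differential set, always genic — couple their host
  gene's log-expression to $\varphi$ with slope ±3. 80% of planted sites
  enter the known-site catalogue, padded with 10% decoy positions so the
  catalogue branch of the filter is exercised against non-candidates.
* **Determinism.** Every draw derives from `config$seed`; identical configs
  produce byte-identical output files.

What the generator does *not* emulate: read-level artifacts (mapping bias,
strand bias, error profiles), batch effects, correlated editing within
Alu-like repeats, and library-size variation. Passing recovery tests
therefore shows the statistics behave correctly under the stated noise
model — not that the pipeline is robust to alignment pathology.

## Problem sizes and observed behavior

The test suite and the acceptance script run the generator at the design
scale above (3000 sites, 24 samples) for recovery, at 2000 sites with all
effects zeroed for null calibration, and at a few hundred sites for unit
checks; a full run of either takes on the order of a minute on a laptop
core. Numbers quoted anywhere in the documentation are produced by those
runs — nothing is asserted that the code does not compute.

* Null calibration: the fraction of raw KW p-values below 0.05, and of cis
  Spearman p-values below 0.05, each land within 3 binomial SE of 5%.
* Recovery at default conditions (seed 1): 38/40 planted differential sites
  reach raw $p<0.05$ while the false-positive rate among unplanted sites
  stays at ~5%; 3/6 planted cis couplings reach $p<0.05$ — the misses are
  sites whose low baseline level leaves too little editing variance to
  propagate into expression, which is the honest behavior of the design,
  not a defect.
* Motif: −1/G odds ratio ≈ 0.15 (depleted), +1/G ≈ 4.4 (enriched), both
  far below the 0.05 adjusted-p threshold at 3000 sites.

## Numerical and degenerate-input choices

* All-identical values in a KW test: H = 0, p = 1 (no error).
* Zero-margin Fisher cells: p = 1, odds ratio undefined, flagged.
* Spearman with fewer than 4 complete pairs, or zero rank variance: NA,
  flagged, site skipped with a reason.
* TPM of an all-zero sample: NA column, listed in an attribute.
* PCA on a zero-variance matrix: explicit error; rank-deficient matrices
  are fine (trailing components get 0% variance).
* Known-site matching is exact on (chrom, pos, strand); position-only
  matching is available because public catalogues differ in strand
  conventions.
* Coordinates are 1-based fully closed everywhere (GTF/VCF convention);
  position 0 in any input is rejected with the offending line number.

## Known limitations

* One consequence call per site under a fixed severity order; bifunctional
  transcripts (coding isoform plus retained non-coding isoform) will
  resolve to the coding call, which can differ from what a multi-isoform
  annotator reports.
* The Fisher background is mononucleotide; context enrichment at positions
  adjacent to the planted motif can show mild spillover.
* The cis scan tests each site marginally; co-edited sites in one gene are
  not jointly modeled.
* The pipeline starts at base counts; no attempt is made to recover sites
  the variant caller never emitted.
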