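---
title: "Whole-genome bisulfite methylome analysis with methscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome bisulfite methylome analysis with methscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methscape)
```

## The problem

Sodium bisulfite converts unmethylated cytosine to uracil (sequenced as T)
while leaving 5-methylcytosine intact, so after aligning bisulfite-treated
reads to a reference, the C/T ratio at each reference cytosine estimates its
methylation level. In plants, methylation occurs in three sequence contexts —
CG, CHG and CHH (H = A, C or T) — maintained by different enzyme families and
carrying different regulatory signals. This package implements the full
desk-side analysis of such data for a two-or-more-stage developmental design:
context annotation of the genome, count extraction from alignments, binary
methylation calling, genome-scale landscape summaries, detection of
differentially methylated regions (DMRs) between stages, association of DMRs
with genes and transposable elements, and cross-referencing with expression
and 24-nt siRNA data. A ground-truthed simulator generates data with the
statistical structure of a typical allotetraploid crop methylome so that
every stage of the pipeline can be benchmarked end to end.

## Cytosine context and coordinates

`enumerate_cytosines()` emits every cytosine on both strands (reference C on
"+", reference G on "-") with its context read 5'->3' on the cytosine's own
strand, plus a 9-bp reference neighbourhood (cytosine at position 5) used for
composition analyses. Conventions:

* Coordinates are 1-based inclusive throughout, matching R/Bioconductor
  practice and the 1-based text reports the package writes.
* A cytosine followed immediately by G is CG even when the third base is
  unknown — the dinucleotide fully determines the context. Otherwise any N or
  missing follower makes the context `NA`, and `NA`-context sites are
  excluded from every downstream denominator; non-ACGTN IUPAC codes map to N
  by default rather than inventing a context.
* The two strands of a symmetric CG dinucleotide are kept as separate sites.
  `call_dmrs(merge_cg_strands = TRUE)` provides the pooled alternative.

## Counting and calling methylation

`extract_counts()` assigns each alignment to a bisulfite strand (the `XG` tag
when present, otherwise FLAG-based inference for a directional library) and
counts C/T bases at "+" sites from original-top reads and G/A bases at "-"
sites from original-bottom reads. Duplicate-flagged reads and reads under
MAPQ 10 are skipped (both configurable); where mates overlap, the base with
the higher quality is counted once, avoiding pseudo-replication.

A site's methylation level is `n_meth / (n_meth + n_unmeth)`. The binary
"methylated site" call used by the landscape fractions and by the DMR
caller's site chaining is a one-sided binomial test of `n_meth` against the
bisulfite conversion-failure rate (default 0.005), BH-corrected across sites
at FDR 0.01. The level deserves a note: at ~27x depth a raw per-site test at
0.05 realises a type-I rate of about 0.8% (two unconverted reads among ~27
already look significant), and with tens of thousands of cytosines that
contamination visibly inflates the smallest context fraction of interest —
CHH, a few percent in this regime. An FDR of 1% keeps false mC calls roughly
an order of magnitude below it. `correct = "none"` and the permissive
`mode = "any"` (any unconverted read) remain available. Even so, binary
calling at finite depth is not unbiased: truly methylated CHH sites with
levels near 0.1 need three unconverted reads to clear the corrected
threshold and a few percent of them are missed; the acceptance suite
measures this honestly rather than hiding it (see the test on global-fraction
recovery).

## Landscape summaries

`global_fractions()` reports the methylated-site fraction per context under
both denominators the field uses (covered sites; all sites).
`level_histogram()` bins methylated-site levels into ten right-closed bins of
width 0.1. `neighborhood_composition()` contrasts the 9-bp base composition
of methylated vs all covered cytosines per context.

`metagene_profile()` uses a fixed geometry: 2-kb flanks in 100-bp bins (20
per flank) and 20 proportional body bins, oriented 5'->3' by feature strand.
A fixed 100-bp interval cannot apply verbatim to variable-length bodies, so
bodies use proportional bins — standard metagene practice; the counts are
configurable. Per-bin values pool covered sites across features
(site-weighted); per-bin site counts are reported so a per-feature-weighted
variant can be derived. Empty bins carry `NA`, never fabricated zeros. The
"-" strand body bin is defined as the exact mirror (`B + 1 - bin`) of the
"+" strand bin so that reversing a feature's strand reverses its profile
exactly, including at body widths not divisible by the bin count. Expression
stratification partitions genes at RPKM 1, 10 and 100 into none / low /
medium / high; the outer bounds follow the usual "RPKM <= 1 is unexpressed"
and ">= 100 is high" conventions, and the interior boundary at 10 is a
declared package default.

## The DMR caller

For one context and two samples, a region is a DMR when it satisfies all of:

(a) at least 5 methylated cytosines in at least one sample;
(b) mean per-site read depth strictly greater than 10 in both samples;
(c) adjacent methylated sites (union over both samples) less than 200 bp
    apart;
(d) span (first to last site, 1-based inclusive) between 40 and 10,000 bp;
(e) a pooled methylation-level difference of at least two-fold with a
    Pearson chi-square p <= 0.05 on the pooled 2x2 counts (no continuity
    correction, no multiple-testing correction by default; BH optional).

"Difference of at least two" is implemented as a ratio of pooled levels, with
a zero denominator floored at `1/(pooled reads + 1)`; an absolute-difference
mode (>= 0.2) sits behind `effect = "absdiff"`. The coverage rule is mean
per-site depth, strictly greater than 10.

Candidate regions are maximal chains of union methylated sites under rule
(c). One structural point needed a design decision: in a typical plant
methylome 60-80% of CG/CHG sites are methylated and sit ~20 bp apart, so
maximal chains run for kilobases to whole chromosomes. Testing a chain as a
unit pools any localised difference against unchanged background, and the
fold-change criterion then fails no matter how strong the local effect. The
caller therefore localises within each chain before testing: sites whose
per-site chi-square between the samples has p <= 0.05 seed sub-chains under
the same <200 bp gap rule, and each seed span is trimmed to its outermost
*strict* seed (p <= 0.01) before criteria (a)-(e) are applied to it
unchanged. The two-level (lenient chain / strict trim) hysteresis keeps a
true segment from fragmenting while preventing isolated boundary noise from
stretching a segment into background and diluting its fold change. A chain
that is differential throughout is tested as itself, so on sparse inputs the
caller reduces to the plain chain definition. The seed levels are fixed
independently of the region-level `alpha` so that tightening `alpha` (or
raising the fold threshold) can only remove calls, never add them.

Chains longer than 10 kb pass through the same localisation (segments are
clipped to the length bounds) rather than being discarded outright —
discarding would silence exactly the saturated backgrounds described above.

`audit_dmrs()` is a deliberately independent re-implementation (plain
per-region loops, `stats::chisq.test`) that re-verifies all five criteria on
every emitted DMR; the test suite runs it across dozens of simulated
comparisons and requires zero violations.

Hyper/hypo labels follow the ordered comparison "test:reference": a DMR is
hypermethylated when the test sample's pooled level exceeds the reference's.
`associate_dmrs()` assigns each DMR to every (feature, zone) it overlaps by
at least 1 bp — body, 2-kb upstream (up2k) or 2-kb downstream (down2k),
strand-oriented — and the summary table counts each DMR once per feature with
body > up2k > down2k priority.

## Integration

`dmr_deg_intersection()` crosses DMR-associated genes with a differential
expression table (up: log2FC > 1 and FDR < 0.05; down mirrored), reporting
per-context counts and cross-context overlaps; ids are matched exactly after
whitespace/case normalisation, and a gene carrying both hyper- and
hypomethylated DMRs appears in both tallies. `sirna_positional_abundance()`
counts 24-nt siRNA loci (midpoint assignment) in the shared metagene
geometry, and `sirna_dmr_overlap()` tabulates loci inside hyper- vs
hypomethylated DMRs per context.

## The simulator

`simulate_bundle()` draws, under one master seed: a 200-kb two-chromosome
genome at GC 0.35 with non-overlapping genes and class-labelled TEs (>= 2 kb
clearance so every gene has clean flank zones); a baseline methylome with
per-context methylated-site probabilities 0.81 (CG), 0.64 (CHG) and 0.05
(CHH); site-level distributions that are bimodal-high for CG/CHG (a
dominant component centred above 0.9 plus a broad minority component) and
broad 0.1-0.4 for CHH (`0.1 + 0.3 x Beta(2, 2)`); Poisson(27) per-site
depth; conversion-failure noise at 0.005; and stage-specific spiked DMRs
(defaults: 20 CG, 10 CHG, 10 CHH; fold 2.5; spans 200-2,000 bp; CG/CHG
spikes hypomethylate the later stage by division, CHH spikes multiply with
an additive fallback where the product would exceed 1). These defaults are
the study conditions the package is benchmarked under, not tuning knobs.
Counts are binomial draws at
`p = level (1 - err) + (1 - level) x conversion_failure`; 125-bp proper read
pairs can be emitted pre-aligned (SAM, directional library, `XG` tags, 300-bp
inserts so mates never overlap), sharing their per-read Bernoulli draws with
an emitted count table so a faithful extractor must agree exactly at error
rate 0. Expression tables honour exact DEG quotas, and an optional coupling
sets CHG body truth to 0.3 in unexpressed vs 0.05 in expressed gene bodies.
A truth set (per-site levels per stage, spike intervals, gene classes) is
written alongside for recovery benchmarking.

What the simulator does *not* emulate: PCR duplicates, base-quality-dependent
errors, M-bias along reads, chromosome-scale methylation gradients,
subgenome asymmetry, or biological replication. Passing tests therefore
demonstrate correctness of the measurement and calling machinery under the
stated statistical regime, not robustness to every artefact of real
libraries.

## Problem sizes and numerical choices

The test suite works at the scales the analyses describe: 200-kb genomes for
landscape-level checks (roughly 70,000 cytosine sites), 20-kb genomes for
the repeated DMR comparisons, 1,000 random kilobase sequences for the
context oracle, and ten 200-kb replicates for spike recovery. Histogram bins
are right-closed; ties in zone priority are fixed (body first); degenerate
chi-square margins return p = 1 with a flag; uncovered sites propagate `NA`
levels, never zeros; all outputs are written deterministically (fixed column
order, no timestamps) so identical configs produce byte-identical files.

## Known limitations

* Binary site calling at ~27x cannot be simultaneously unbiased for a 5%
  CHH regime and strict about conversion-failure noise; the residual
  deficit (about -0.3 to -0.5 percentage points on mCHH/CHH) is quantified
  by the acceptance suite.
* The caller assumes two samples without biological replicates — as in
  single-replicate staged designs — so its p-values describe sampling noise,
  not biological variance.
* Gene parts (CDS vs intron) are supported through the feature-class
  summary only; no per-exon methylation model is fitted.
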