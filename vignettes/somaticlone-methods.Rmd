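---
title: "Methods: clone-based somatic mutation inference and CpG indel annotation"
author: "somaticlone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clone-based somatic mutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticlone)
```

## The inference problem

When a single somatic genome is clonally amplified — for example by
establishing an embryonic stem cell line from a nuclear-transfer embryo that
received one neuron's nucleus — every mutation present in the founding
nucleus is propagated to all cells of the clone. A heterozygous somatic
mutation therefore appears at a variant allele frequency (VAF) near 50% in
whole-genome sequencing of that clone, while mutations acquired during
establishment or culture of the line appear at lower, subclonal VAFs.
Sequencing several *sister* clones derived from the same animal adds a second
discriminator: mutations present in the donor animal's early lineage are
shared across sister clones, whereas a mutation that arose in the single
donor cell is unique to one clone.

`somaticlone` implements this inference and the downstream characterization
of the calls: callable-region construction, VAF-based clone-unique
filtering, indel normalization and repeat-context classification,
CpG-proximity and CpG gain/loss annotation, templated-duplication and
junction-microhomology detection, SBS96/ID83 signature matrices with NNLS
refitting, and interval/gene-model enrichment statistics. A synthetic-data
generator with machine-readable truth tables makes every step testable by
parameter recovery.

## Callable regions (effective whole-genome coverage)

Mutation counts are only comparable across clones where all clones are
adequately and uniquely mappable. A position is *callable* for a sample
when

1. its depth in high-confidence reads (properly paired, mapping quality 60,
   unclipped; the "MQ60" track) lies within 50–300% of the chromosome's
   peak coverage,
2. the ratio of MQ60 depth to all-mapped-read depth is at least 80%, and
3. the base-quality mask (minimum base quality 20, consumed as a
   precomputed track) passes.

The callable sets of all samples are intersected and only the shared
regions enter mutation analysis (`ewcRegions()`, `intersectEwc()`).
Numerical choices the criteria do not pin down:

* **Peak** is the mode of the integer MQ60 depth histogram over nonzero
  positions, computed per chromosome on the raw histogram (no smoothing).
  Ties break toward the *lower* depth, which widens the exclusion of
  suspicious high-depth regions.
* **Depth-window boundaries are inclusive** on both ends
  (depth $\in [0.5\,p,\ 3\,p]$), reading "within 50 to 300%" as a closed
  interval.
* Sites with zero all-mapped depth fail the ratio criterion (uncallable).

## The clone-unique filter

For each candidate site, per-clone VAF is `AD_alt / DP`, undefined when
`DP = 0`. With thresholds $t_u = 0.30$ and $t_s = 0.01$ (strict
inequalities, as stated):

* **shared** — at least 2 clones have VAF $> t_u$;
* **unique(c)** — exactly one carrier clone $c$, and every *sister* clone
  (same animal) has a defined VAF $< t_s$;
* **ambiguous** — a carrier's sister is uncallable or falls in the gray
  zone $[t_s, t_u]$, or, with no carrier, any clone does;
* **absent** — otherwise.

Design choices: the sister set is restricted to clones of the same animal;
clones of other animals are ignored for uniqueness (a cross-animal
panel-of-normals is deliberately not applied by default). Sites with a
sister VAF in $[1\%, 30\%)$ are a gray zone the thresholds do not cover; we
label them ambiguous and exclude them from every downstream count, which
mirrors a conservative manual-inspection step. Deletions must fit their
whole deleted span inside the shared callable regions, insertions their
anchor and the following base: an indel call needs callable flanks.

At the design depth (mean 40), the carrier rule has an exact binomial miss
probability: $\Pr(\mathrm{VAF} \le 0.30)$ averaged over a zero-truncated
Poisson(40) depth is ≈ 0.7% per site, so truth-recovery experiments are
asserted at ≥ 99%, not 100%.

## Indel annotation

All indels are first reduced to a minimal anchored representation and
left-aligned (`normalizeIndel()`); every annotation below is invariant to
the input representation because it only sees the normalized form.

**Repeat context.** An indel is *homopolymer* when it lies in or extends a
single-base reference run of ≥ 5 bases; else *tandem_repeat* when a 2–6 bp
motif repeated ≥ 5 times in the reference contains or directly abuts
(within 1 bp) the site and the indel sequence is a whole number of motif
copies; else *nonrepeat*. The "≥ 5 copies" rule is the study's repeat
definition; the 2–6 bp motif bound is the microsatellite convention and is
exposed as a parameter (`max_motif`), as is the copy threshold. Precedence
is homopolymer > tandem_repeat > nonrepeat, and the classes are mutually
exclusive.

**Site conventions.** The insertion site is the inter-base gap after the
normalized anchor; the deletion site is the closed deleted span. A CpG
"within w bp" of an insertion means a CG start in $[a+1-w,\ a+w]$ around
anchor $a$; for a deletion, the CG footprint must intersect the span
extended by $w$ on both sides — CpGs wholly inside the deleted bases count
(they are at the site, and they count toward loss). A breakpoint-wise
window for deletions is available via `del_mode = "breakpoints"`.

**CpG gain/loss** applies the allele edit to the ±10 bp window string and
counts CG dinucleotides before and after, tracking site identity by
aligning CG start coordinates outside the edit; `gain − loss` always equals
the net change.

**Duplications.** An insertion is a templated duplication when the inserted
sequence equals (case-insensitively) the same-length reference substring
immediately 3′ of the insertion point — the signature of a templated
insertion.

**Microhomology** of a deletion is the longer of the two junction matches —
deleted-prefix vs downstream flank, deleted-suffix vs upstream flank —
capped at the deletion length. A deletion whose full length matches a flank
is representation-degenerate with a repeat contraction and carries a
`full_homology` flag.

## Signature matrices and refitting

`sbs96Matrix()` maps each SNV to the pyrimidine-centered trinucleotide
alphabet (purine-reference SNVs are reverse-complemented; the alphabet
order is the conventional six substitution classes × 16 flank contexts).
`id83Matrix()` implements the COSMIC v3 indel scheme as a versioned,
documented constant: 1 bp events by base and homopolymer length, longer
events by length and tandem-unit count, non-repeat deletions by junction
microhomology. Column sums conserve input counts; unclassifiable events
(non-ACGT content, contig edges) are excluded and logged.

Refitting (`refitSignatures()`) solves, per sample, the non-negative least
squares problem $\min_{w \ge 0} \lVert Rw - c \rVert_2$ against a reference
catalog, normalizes $w$ to proportions, zeroes contributions below 0.05 and
re-solves once on the surviving signatures. This deliberately replaces de
novo NMF extraction: refitting against a fixed catalog answers "which known
signatures explain the spectrum", which is the reported quantity; de novo
extraction is out of scope. `syntheticSignatureCatalog()` provides a
clearly-labelled synthetic catalog (peaked, largely disjoint supports) for
demonstrations and recovery experiments; real catalogs are read from TSV
with `readSignatureCatalog()`, and no network access is ever attempted.

## Group statistics

Summaries are means ± sample SD (n−1 denominator). Fold changes are ratios
of per-clone group means (ko/wt), and significance uses Welch's unequal
variance t test with Satterthwaite degrees of freedom, two-sided, with no
multiple-testing correction (raw p-values are the reported quantity). The
closed form is implemented directly and tested to 10⁻¹⁰ against
`stats::t.test`. Degenerate cases are reported without a p-value and with a
reason (`zero_variance`, `group_too_small`). The promoter category in
genomic-region annotation is 2 kb upstream of the TSS (configurable; the
category precedence is 5′UTR > 3′UTR > coding exon > intron > promoter >
intergenic).

## The synthetic-data generator

The generator emulates the clonal study design: two wild-type animals
contributing 7 clones and two knockout animals contributing 8, shared
early-lineage SNVs per animal, and clone-unique SNVs and indels at
per-genotype Poisson rates. The default `cloneDesign()` encodes the study
conditions: 76/62 SNVs and 123/111 indels per wt/ko clone; nonrepeat
insertions 1.7/7.3 and deletions 2.7/6.8 per clone; duplication
probabilities 0.75/1.0 for nonrepeat insertions; CpG targeting such that
most ko nonrepeat indels fall within ±2 bp of a CpG while few wt ones do;
junction-microhomology length distributions with ~ 2/3 of ko deletions
carrying microhomology; insertion sizes 4.2 ± 3.5 (wt) vs 7.3 ± 3.7 bp
(ko), deletion sizes ≈ 5 ± 5 bp. Where the study reports only a fraction
(e.g. 36/52 deletions with microhomology), the length distribution behind
it is a package choice: a decreasing distribution over 0–4+ bp consistent
with the reported fraction.

Mechanics and their rationale:

* Background sequence is i.i.d. at 42% GC. DMRs are built by planting CG
  dinucleotides at a target density (default 8/100 bp) into the background;
  this makes CpG enrichment a controlled dial that can be verified by
  direct string counting on the output.
* Repeat tracts (homopolymers and primitive 2–4 bp tandem motifs, 8 copies)
  are planted with sealed boundaries so copy numbers are exact; repeat
  indels are whole-motif-copy edits at tract left edges, already
  left-aligned. Tracts are planted because the design asks for a controlled
  fraction of indels in repeat context, and i.i.d. sequence contains almost
  no long tandem repeats. Repeat indels are placed before free-floating
  variants so the spacing rule cannot starve them of tracts.
* Nonrepeat deletions are placed by rejection sampling until the brute-scan
  junction microhomology equals the drawn target exactly; nonrepeat
  insertions are either copies of the downstream reference (duplications)
  or random sequence verified not to be one. All placements are verified
  nonrepeat by an independent scan at plant time, keep a 200 bp margin from
  chromosome ends (so ±100 bp windows are always defined), and a 150 bp
  minimum spacing so window annotations of neighbouring variants cannot
  interact. Placement resamples up to a cap and then errors, rather than
  silently degrading the design.
* Read support: depth per clone-site is zero-truncated Poisson
  (the simplest model matching WGS depth marginals);
  alt reads are Binomial(DP, VAF′) with VAF′ = (1−c)·0.5 in carriers and
  c·0.5 in non-carriers, modelling cross-clone contamination at the VAF
  level — the only level the filter sees. The contamination level
  distinguishing "< 1% in sisters" is not pinned by the filter definition,
  so it is an explicit parameter (default 0) rather than a constant.
* Depth tracks are constant at the design depth, so the peak is exact and,
  absent artifacts, the callable fraction is 1; each planted artifact
  (dropout, spike, low-MQ-ratio, base-quality fail) violates exactly one
  callable-region criterion, which makes the exclusion test exact.
* All outputs (FASTA, VCF with AD/DP, BED, TSV truth table, JSON manifest)
  are byte-deterministic given the seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: sequencing error and mapping artifacts (alt reads in
non-carriers arise only through the contamination parameter), GC-dependent
and positionally autocorrelated coverage, mutational spectra (SNV
substitution types are uniform, so simulated SBS96 matrices are flat),
aneuploidy and structural variation, and the phylogenetic structure of
shared mutations beyond a single shared-per-animal set.

## Problem sizes and identifiability choices

The test suite and the acceptance script run the full clonal design (15
clones, ≈ 2,900 planted variants on a 2 × 1.5 Mb genome), the annotation
oracle comparison at 10,000 planted indels on a 2 × 2.25 Mb genome, 100
mixture-recovery refits at 500 sampled mutations each, and 100 seeded
fold-change recovery runs on a 450 kb genome. These sizes were chosen so
that every stochastic assertion sits several standard errors from its
threshold under the design conditions.

Two statistically-motivated choices deserve note. First, the fold-change
recovery experiment plants its 4× knockout/wild-type difference in the
nonrepeat insertion rate at 80 vs 20 events per clone rather than at the
study-scale 7.3 vs 1.7: the analytic relative standard error of a ratio of
Poisson group means at 8 + 7 clones is ≈ 31% at study-scale rates — the
fold is simply not identifiable to ±25% there — and ≈ 9% at the chosen
rates. The experiment tests recovery of the *fold*, which is held at 4×.
Second, the mixture-recovery criterion is asserted on the Monte-Carlo mean
of the recovered weight across the 100 replicates (and on the mean absolute
error): the per-replicate sampling SD of a 0.7/0.3 multinomial mixture
weight at n = 500 is ≈ 0.02 for an ideal estimator, so a per-replicate
bound of ±0.05 on all 100 replicates would fail a perfect estimator a
quarter of the time by sampling alone.

## Known limitations

* The pipeline consumes depth *tracks*, not BAMs: extraction of
  highly-reliable reads and per-base quality masks is upstream.
* Only biallelic candidate records are supported; multiallelic records
  must be split and normalized upstream.
* The ambiguous gray zone ($[1\%, 30\%)$ sister VAF) is excluded rather
  than adjudicated; on real data a visual-inspection or error-model step
  would refine it, and counts on real data may differ accordingly.
* Structural variants and mobile element insertions are out of scope, as
  are de novo signature extraction, motif discovery and GO enrichment.
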