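---
title: "Genotyping insecticide-resistance markers from multiplexed amplicon sequencing"
author: "ampliresist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping insecticide-resistance markers from multiplexed amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliresist)
```

## The assay and its analysis

Targeted amplicon sequencing genotypes known resistance mutations in
*Anopheles* populations cheaply and at scale. PCR primers flanking each
marker region (~500 bp products across the *vgsc*, *rdl*, *ace1* and
*gste2* genes) carry 5′ barcode tags of 8 bp; every mosquito gets a
unique (forward, reverse) barcode combination, products are pooled and
sequenced paired-end 2 × 250 bp, and the analysis walks back from pooled
reads to per-mosquito genotypes:

1. **Demultiplex** by the leading 8-mers of both mates. A pair is
   assigned only when exactly one sample's barcode pair matches; with
   1-mismatch matching enabled, pairs compatible with two samples are
   discarded as ambiguous rather than guessed. Exact matching is the
   default — with barcode sets kept ≥ 4 substitutions apart, a single
   sequencing error in a barcode loses a read rather than misassigning
   it.
2. **Trim** with sliding-window semantics: remove leading and trailing
   bases below Q3, scan 5′→3′ in 4-base windows and cut at the first
   window whose mean quality falls below 20 (windows truncated at the
   read end use the bases available), then drop reads shorter than
   36 bp. A pair is excluded when either mate is dropped; amplicon data
   are deep enough that orphan rescue buys nothing.
3. **Align** to the amplicon panel only. Reads are known amplicon
   products, so whole-genome mapping is replaced by shared-15-mer voting
   for the candidate amplicon and diagonal, then a banded (±10)
   affine-gap alignment, global in the read and local in the reference
   (match +1, mismatch −2, first gap base −5, extension −1). Both
   orientations are tried, since mate 1 always reads from the
   forward-primer end and mate 2 from the reverse. Reads matching fewer
   than 80% of their bases are discarded. The banded score is checked
   against an unbanded dynamic-programming aligner in the test suite.
4. **Pile up** with a strict per-base filter: a base counts only when
   its phred score exceeds 30. Where trimmed mates of one pair overlap
   mid-amplicon, each position is counted once and the
   higher-quality base wins — double-counting would inflate depth
   two-fold exactly where many targets sit. Bases within 3 bp of an
   alignment gap are excluded (indel shadow).
5. **Call** per sample with two independent detectors: a frequency
   caller (top non-reference base ≥ 5% of passing depth) and a binomial
   caller (alternate count inconsistent with a 0.5% error rate at
   α = 10⁻³). A site survives only when *both* flag it — the
   combination is read as an intersection, the conservative
   interpretation; a union mode is available — and when the sample's
   alternate depth is ≥ 10 and passing depth ≥ 30.
6. **Genotype** from the alternate-read fraction: `< 25%` homozygous
   reference, `25–75%` (both boundaries inclusive) heterozygous,
   `> 75%` homozygous alternate. Samples below 30× at a site are
   no-calls and leave the denominator.
7. **Retain** sites carried by more than one sample, and remove
   species-specific sites so species composition cannot masquerade as a
   resistance signal. The published analyses do not define
   "species-specific" operationally; this package uses: alternate
   frequency ≥ 0.95 within one species and ≤ 0.05 in every other
   species with at least 5 called samples (all three thresholds
   configurable).
8. **Summarise**: per-stratum genotype counts, allele frequencies
   (het/2 + hom_alt, denominators = 2 × called samples at that site),
   pairwise Pearson χ² on 2 × 2 allele-count tables (df = 1, Yates
   correction on by default — the default R behaviour for 2 × 2
   tables — and recorded in every result so reports are
   self-describing; raw p-values by default, Bonferroni available), and
   per-sample counts of carried target mutations per gene.

Indels may be detected by the aligner but are never genotyped; the
analysis surface of this assay is SNPs.

## Coordinates, gene models and residue numbering

All coordinates are 1-based, fully closed (VCF convention);
amplicon-local position *p* maps to genome position
`amplicon_start + p − 1`. Each amplicon carries a gene model (exons,
strand, phase, codon-numbering offset). The offset makes the reported
residue numbers match the names the field uses — the *kdr* codon is
"995" in the *An. gambiae* numbering even though the amplicon models
only 140 codons. Loading a panel re-derives every target's amino-acid
label by translating the reference and substituted codons through the
model, on either strand, so a mislabelled or misplaced target is a load
error, not a silent mismatch.

## The demonstration panel is synthetic

The real chromosome sequences are not shipped. The bundled panel mirrors
the seven-amplicon design: deterministic pseudo-random 470-bp backbones
with the reference codons of interest written in at the correct
positions, gene models (including a minus-strand gene, *gste2*, and an
intron-bearing one, *ace1*) whose codon offsets reproduce published
residue numbers, and genome coordinates anchored to published marker
positions. Amplicons are 470 bp rather than ~500 so that 250-bp reads
minus the 8-bp barcode (242 bp per mate) cover every base with a 14-bp
mate overlap — the real design achieves full coverage the same way, by
mates overlapping mid-amplicon. Of the 17 targets, ten are the named
published markers (L995F, L995S, N1570Y, A1746S, A296G, G280S, I114T,
L119F, L119V, F120L); the remaining seven fill the panel at plausible
published-residue positions and are synthetic placeholders. The IGS
speciation templates are likewise synthetic sequences constructed so
that in-silico PCR and HhaI digestion reproduce the printed diagnostic
bands exactly; they are labelled `synthetic` in the shipped FASTA.

## What the simulator emulates — and what it does not

`sim_config()` describes a cohort: per-target true allele frequencies,
mean per-amplicon read-pair depth (Poisson-distributed per
sample-amplicon), 2 × 250 bp reads carrying barcode + template,
i.i.d. substitution errors (default 0.2%), and a per-base quality
profile (default mean Q35, sd 3, 0.01/base 3′ decay). Genotypes are
drawn Binomial(2, *p*) — Hardy–Weinberg, an assumption made here for
synthetic data only, not asserted of real populations. Heterozygotes
place the alternate allele on each fragment with probability 0.5, with
both mates of a fragment agreeing. A fixed seed makes the whole
simulation byte-identical.

Deliberately not modelled: PCR chimeras and polymerase errors, index
hopping, duplicates, indels, depth over-dispersion beyond Poisson,
primer-site mismatches, and contamination from off-target loci.
Passing end-to-end tests therefore demonstrate that the pipeline's
logic is faithful (demultiplexing, trimming, alignment arithmetic,
depth accounting, caller thresholds, genotype and frequency algebra) —
not that it is robust to every artefact of real MiSeq data.

## Numerical conventions and degenerate inputs

* Phred qualities are integers (Sanger +33); the pileup cutoff is a
  strict `> 30`.
* Genotype boundaries 0.25 and 0.75 are heterozygous (the published
  rule writes both homozygote classes with strict inequalities).
* Report tables round to one decimal, half away from zero — the
  convention that reproduces the published tables — and render
  zero-frequency strata as "–"; full precision is kept internally.
* χ² on a table with a zero margin returns an explicit degenerate
  result (NA statistic and p) rather than NaN.
* Ties in the aligner's k-mer vote resolve to the first amplicon in
  panel order; candidate alternate alleles tie-break to the
  first-in-A,C,G,T order via `which.max`. Only the single
  highest-count alternate is genotyped per site per sample (the
  genotype rule is biallelic); further alternates surface in logs.
* An empty read, a read shorter than the seed k-mer, or a column of
  depth 0 are all well-defined no-ops (dropped / unaligned / no call).

## Problem sizes

The shipped tests and the acceptance script run cohorts of 2–150
mosquitoes at 20–200× depth (up to ~2 × 10⁵ read pairs), sizes chosen so
the full suite completes in a few minutes on a single core while still
exercising two sequencing pools and every pipeline stage at realistic
depth. The Rcpp kernels scale linearly in read count; nothing in the
design caps cohort size.

## Known limitations

* The internal callers implement stated contracts (frequency threshold;
  binomial error test). They are not re-implementations of Freebayes or
  HaplotypeCaller, and no fidelity to those tools is claimed — the
  genotype rule consumes allele depths, which all callers here supply
  identically from the same pileup.
* Off-panel contamination filtering (reads from loci outside the seven
  amplicons) is limited to the 80% identity gate; a whole-genome mapper
  would reject such reads more specifically.
* Species-specific-site removal needs several called samples per
  species to act; tiny cohorts simply retain those sites.
* In-silico PCR uses exact primer matching by default; real-world
  primer-template mismatches (e.g. degraded or divergent templates) are
  out of scope, though a mismatch allowance exists.
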