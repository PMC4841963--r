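---
title: "Genic marker discovery from multi-species transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genic marker discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genepoolmarkers)
```

## The problem

Crop breeding across a genepool — a cultivated species plus its
cross-compatible wild and cultivated relatives — needs two kinds of genic
markers: microsatellites (SSRs), whose length polymorphisms are scored by
fragment analysis, and single-nucleotide variants (SNPs and short INDELs),
scored by melting analysis, arrays or CAPS digestion. Transcriptome
assemblies provide the sequence substrate; the analytical work is (a)
finding the features, (b) deciding which species they distinguish, and (c)
deciding which are *practically genotypable*. This package implements that
analysis as a deterministic, testable pipeline over standard formats
(FASTA, BED, VCF, TSV), with every coordinate 0-based and half-open
internally; only the VCF boundary converts to and from 1-based positions.

## SSR mining

An SSR hit is a **maximal perfect tandem tract of complete motif copies**:
`tract_length = repeat_count × motif_length`, with class thresholds di ≥ 9,
tri ≥ 6, tetra ≥ 4 complete copies (minimum reportable tract 16 nt). The
scanner compares each base with the base one period ahead and extracts runs;
complete-copy trimming anchors tracts at their leftmost phase.

Motifs are canonicalized into families: the canonical motif is the
lexicographically smallest rotation of the motif or of its reverse
complement, and the family label is `canonical/revcomp(canonical)`
(AG/CT, AAG/CTT, …). Motifs that are whole powers of shorter units are
rejected, which also excludes all mononucleotide runs. Tracts are broken at
N.

Three design points were genuinely open:

- **Imperfect repeats.** The original mining tool family permits imperfect
  repeats through a mismatch-scoring scheme, but only motif-count thresholds
  are specified for this analysis, and the observed minimum tract length
  (16 nt = 4 × 4) is exactly the perfect-tract bound. We adopt perfect
  repeats with complete copies: it is reproducible, parameter-free and
  brute-force checkable.
- **Overlaps across classes.** When tracts of different classes overlap
  (e.g. a dinucleotide run embedded in a tetranucleotide context), the
  longer tract wins; ties go to the smaller motif, then the leftmost start.
  One hit per locus keeps the count tables meaningful.
- **Phase ties within a class.** A periodic region admits several complete-
  copy anchorings of equal length; the leftmost is reported, and the
  brute-force oracle applies the same rule.

## SSR localization

With a transcript's single principal ORF `[start, end)` and strand, a tract
fully inside the ORF is `ORF`; fully between the transcript start and the
ORF is `FIVE_UTR` on the plus strand and `THREE_UTR` on the minus strand
(and symmetrically for the other side). Tracts that straddle an ORF
boundary, and all tracts on ORF-less transcripts, fall into `OTHER` — the
"no precise position" bucket. Majority-overlap assignment was considered
and rejected: the straddle rule is deterministic and makes the partition
property (categories sum to the hit count) trivially checkable, and a
strand flip swaps the two UTR categories exactly.

## SNV classification

The kind split is purely allelic: a site is a SNP iff REF and every ALT are
single bases; otherwise it is an INDEL.

Species-level classification works on genotypes keyed by species through a
sample panel:

- a species is **heterozygous** at a site if any of its called samples is
  het; it is **homozygous for allele a** only if all its called samples are
  `a/a`. Discordant homozygous samples leave the species unclassified at
  that site; missing genotypes exclude it from every tag.
- **intraspecific** tags: every heterozygous species.
- **interspecific** tags: every 2-, 3- or 4-way species combination in which
  all members are homozygous and at least two distinct alleles occur.
  Allele identity (including second ALTs at multi-allelic sites) is what is
  compared, not just REF-vs-ALT. Combinations of different sizes are tagged
  independently, and a site het in one species can still be interspecific
  among others.

Requiring *all* members of a k-way combination to be callable and homozygous
is what makes triple and quadruple counts much rarer than pairwise counts in
real data; tagging a pair independently of the state of the non-member
species is an explicit choice (the alternative — conditioning on the other
species being uncallable — is not what the published pair totals suggest).

## The suitability cascade

A variant is retained (`filtered == TRUE`) iff it passes all four filters:

| filter | meaning | default | boundary |
|--------|---------|---------|----------|
| CS60 | another SNV on the same transcript closer than `cs` nt (first-REF-base distance) | 60 nt | 59 flags, 60 passes |
| CL60 | closer than `cl` nt to either transcript edge, `min(pos, len-1-pos)` | 60 nt | 59 flags, 60 passes |
| HV0.05 | some sliding window of `hv_window` nt containing the variant holds more than `hv_max` variants | 100 nt / 5 | 6 variants spanning ≤ 99 nt flag; 5 never flag |
| CEF | some catalogue enzyme digests the two allelic ±`flank` nt contexts into different fragment patterns | 60 nt flank | — |

"Closer than" is read strictly for CS60 and CL60. HV uses *sliding* windows
(any 100-nt window), the conservative reading of "the region"; a fixed-tile
reading would let dense clusters straddle tile borders undetected. The CEF
context of ±60 nt matches the spacing rules and the small amplicon sizes
(80–100 bp) the cascade is designed around; it is a flag, not a constant.

CEF compares **fragment-length multisets**, not just site counts: a SNP that
destroys one recognition site and creates another of the same enzyme
elsewhere in the amplicon leaves the count unchanged but still changes the
banding pattern — and, conversely, it is the banding pattern a CAPS assay
actually reads. Recognition sites are IUPAC-degenerate and matched on both
strands at every overlapping offset (zero-width lookahead regex); the test
suite checks this against a position-by-position lookup-table digestion
oracle. The enzyme catalogue is data, not code: a packaged TSV of 22 common
6-cutters (including two degenerate-site enzymes, AvaI and HincII) that can
be replaced with `--enzymes`.

INDELs go through CEF like SNPs (the published filtered counts include
INDELs); their alt contexts differ in length, which the fragment multiset
handles naturally.

## The synthetic world

The generator emulates the downstream products of a real multi-species
variant-calling experiment — transcripts with ORFs and UTRs, perfect SSR
tracts of known motif and span, and a 4-species VCF of planted heterozygous
and homozygous-differential variants — without any read-level simulation,
mapping or calling. What a green closed loop establishes is that the
pipeline's definitions are mutually consistent and exactly recover planted
truth; it does **not** establish robustness to genotyping error, uneven
coverage or assembly artifacts, which are upstream of this package's scope.

Defaults (the stated world of the closed-loop criterion):

- 200 transcripts, 300–3,000 nt, uniform base composition; background is
  rejection-sampled until it contains *no* tract meeting the mining
  thresholds, so the only minable SSRs are planted ones, and the scan is
  repeated after every sequence edit (SSR planting, CAPS site planting).
- `orf_fraction = 0.45` (about the fraction of unigenes with predicted ORFs
  in the motivating transcriptomes); ORF start in the first third, end in
  the last third, random strand.
- `ssr_plant_rate = 0.8` per transcript, class mix 27/63/10%
  (di/tri/tetra) as observed in genic SSR surveys; copies at threshold + 0–6.
  The rate is set so a 200-transcript world reliably carries ≥ 100 planted
  SSRs. Real transcriptomes carry far fewer (≈1% of unigenes); the closed
  loop needs density, not realism.
- clean variants at 1.2 SNPs and 0.25 INDELs per kb, spaced ≥ 60 nt from
  everything so their intended flags are all-pass; per-transcript
  probabilities then plant the violation constructs: a close pair 20–59 nt
  apart (`p_cs_pair = 0.15`), a near-edge variant (`p_cl_edge = 0.10`) and a
  cluster of six within ≤ 90 nt (`p_hv_cluster = 0.06`). The spec phrased
  violations as a per-SNV fraction; with ~3 variants per transcript a
  fraction cannot assemble a 6-variant cluster, so the construct
  probabilities replace it.
- half of the clean SNPs get a planted restriction site whose ALT breaks it
  (`plant_caps_site`), giving guaranteed CEF positives; all CEF truth values
  (positives and the incidental ones that arise from random context) are
  measured on the final sequence by the generator's own scanner.
- heterozygosity weights `AET 0.40, INC 0.08, MEL 0.02, TOR 0.15` mirror the
  ordering of intraspecific variation in the motivating study (the
  open-pollinated cultivated relative ≫ wild relatives ≫ the inbred crop);
  the remaining mass yields interspecific patterns with random carrier
  subsets, occasional missing genotypes and occasional second ALT alleles.
- one sample per species by default, matching a single-accession design;
  the panel supports more, in which case the same genotype is replicated.

Truth tags are derived from the emitted genotypes by brute-force subset
enumeration at generation time, and truth filter flags by plain per-variant
loops plus a hand-written IUPAC matcher — code paths deliberately separate
from the pipeline's vectorized and regex implementations.

## Numerical and formatting choices

- Percentages print to one decimal. The default is round-half-even, but a
  `"truncate"` mode exists because published one-decimal values mix both
  behaviours (a splice-variant fraction of 18.354 printed as 18.3 is
  truncation; an ORF share of 32.69 printed as 32.7 is rounding). Raw
  counts are always emitted alongside, so rounding never hides information.
- Unigene selection takes the maximum-expression transcript per cluster with
  a lexicographic tie-break; expression units are opaque and only ordering
  matters.
- Degenerate inputs: empty hit lists produce header-only tables; empty
  variant frames produce all-zero category tables; an empty length vector or
  a zero unigene denominator is an error, not an NA.
- Determinism: the generator uses an isolated RNG state (seed in, global
  state restored), all writers emit in binary mode with fixed formatting,
  and identical configs are byte-identical across runs.

## Known limitations

- Variants are consumed in transcript space; projecting genome-space calls
  onto transcripts (as a genome-mapped experiment would need) is out of
  scope, and edge distances are measured to transcript ends.
- Perfect SSRs only: a real mining run allowing imperfect repeats would
  report more and longer tracts.
- The enzyme catalogue is a representative common-cutter set, not the
  (unpublished) exact list of any particular study; CEF outcomes depend on
  it, which is why it is an input.
- No genotype-likelihood or error model: a het miscalled as hom would be
  tagged wrongly, silently. The closed loop assumes perfect genotypes by
  construction.
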