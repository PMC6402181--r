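---
title: "Cross-assembly annotation transfer: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-assembly annotation transfer: models, conventions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftann)
```

## The procedure

Non-model organisms carry little native clinical or functional annotation,
so `liftann` transfers it across assemblies. Each cohort variant is
normalized against its own reference, lifted through a UCSC chain file onto
an annotation-rich target assembly, annotated there, translated back to its
original coordinates, and merged with the records that could not be lifted.
Downstream, gene-context and coding-consequence classification run on the
*source* gene models, and cohort statistics (frequencies, privacy, the
derived allele frequency spectrum, Mendelian validation, a
variants-of-interest list) are computed over the merged stream. The final
product is a single annotated VCF: every input record appears exactly once,
either annotated or tagged with the reason it could not be lifted.

## Coordinate and record conventions

VCF and GFF3 coordinates are 1-based inclusive throughout; chain files are
0-based half-open with strand-relative coordinates exactly as the UCSC
format defines them, and the conversion happens only at the module
boundary. Multi-allelic sites are always decomposed on read: allele-keyed
annotation matching and per-variant statistics need biallelic records. When
a genotype referenced a *different* alternate of the same site, its index
becomes missing rather than reference — decomposition must not fabricate
reference observations. Symbolic alleles and alleles containing `N` are
excluded and counted; structural variants and breakends are out of scope.
A genotype with either haploid index missing is treated as missing for all
frequency purposes.

Normalization trims shared trailing bases, keeps a single anchor base for
indels, and left-aligns indels through repeats by the classic
trim-and-prepend iteration. It is idempotent and sequence-preserving
(applying the edit at the original and at the normalized locus yields the
same chromosome), which is what makes "identical position and allele"
matching well defined on both assemblies.

## Liftover and allele reconciliation

`map_point` maps one base through the chain set: block offset arithmetic,
with minus-strand target coordinates folded back to the forward strand. A
position in a source-side gap reports `SPANS_GAP`; no covering chain is
`NO_CHAIN`; chains that disagree about the destination report
`AMBIGUOUS_MULTIMAP` (chains that agree are accepted — an explicit choice;
an alternative would be highest-score-wins, which we did not take because
silent resolution hides real ambiguity).

`lift_variants` requires the whole ref span — plus the following base for
insertions, so the insertion point itself lies inside one block — to map
contiguously through a single chain. On a strand flip the alleles are
reverse-complemented and the target position is the leftmost lifted base;
because the anchor base of an indel changes sides under reverse complement,
lifted indels are re-normalized against the target genome before any
matching. The target reference is then fetched: equal to the lifted ref is
a clean `LIFTED`; equal to the lifted alt is an `ALLELE_SWAP` — the record
stays annotation-eligible with ref and alt exchanged, the standard
treatment for reference-allele differences between assemblies; anything
else is `REF_MISMATCH`, which is carried through unannotated with its
status. Back-translation uses the original coordinates carried on the
record, never a reverse chain pass: a reverse lift can fail asymmetrically,
whereas carried coordinates are lossless by construction.

## Annotation joins

Sources are keyed stores in target coordinates: allele-keyed tables
(ClinVar-style TSV or VCF), position-keyed numeric scores (SIFT/PolyPhen2/
CADD-style), and interval tracks (BED; any 1-base overlap with the ref span
annotates). Allele-keyed rows are re-normalized with the target genome at
load time so representation differences cannot break identity matching.
Every source writes under its own `MG_<NAME>_<FIELD>` namespace; collisions
are a startup error, and sources are processed in a canonical order so the
result cannot depend on how the configuration listed them. Clinical
significance strings are parsed case-insensitively, composites split on
`/` and `,`; the pathogenic flag is set iff any token is *pathogenic* or
*likely pathogenic*, and unrecognized strings are preserved verbatim under
a raw key without ever setting the flag. Numeric score *thresholds* are
deliberately not applied at join time: what counts as "damaging" is a
configuration value consumed by the prioritization rule, since published
category labels rarely come with printed cutoffs.

## Consequences and impact tiers

Region classification assigns exactly one category per variant with
precedence coding > utr > splice_region > intron > non_coding_gene >
upstream_gene > downstream_gene > intergenic; the up/downstream windows are
5000 bp from the *gene* bounds, strand-aware. The splice region defaults to
the 3 intronic bases flanking each exon boundary (configurable; the
category is conventional rather than standardized). Coding calls compare
codons under the standard genetic code; indels classify by length modulo 3.
Two tie-breaks worth stating: a variant hitting several transcripts or
genes reports the single most severe call (severity = impact tier, ties by
the fixed category order), and an SNV that destroys the initiator codon is
`start_lost` even when the new codon happens to be a stop — the initiator
rule is checked first. Transcripts whose CDS length is not a multiple of 3
are flagged and evaluated on the usable frame only. One practical note: a
single codon must be translated by genetic-code lookup, not by a
translation routine that treats its input as initiator-first, or CTG/TTG
codons silently become methionine.

## Catalog statistics

Frequencies use fully-called diploid genotypes only; `MAF = min(AF, 1-AF)`.
A variant is *private* when exactly one individual carries the alternate —
one homozygous carrier is still one individual, so a private variant has an
allele count of 1 or 2. The derived allele frequency spectrum defaults to
alt-as-derived (reference = ancestral) binned into 20 equal-width bins over
(0, 1]; this polarization is the largest interpretive gap in the procedure,
so an ancestral-allele INFO key is supported as an explicit alternative and
variants whose ancestral allele matches neither allele are excluded and
counted rather than guessed. Mendelian validation is autosomal-biallelic:
a full trio is consistent iff the child's alleles can be partitioned
between the parents; a duo is consistent iff the child shares an allele
with the parent or is heterozygous; any missing genotype skips the family.
The default violation-rate threshold is 0 — any violation flags the
variant, nothing is removed — because a defensible published cutoff is not
available. The variants-of-interest rule is a pure union (clinically
pathogenic, or HIGH impact, or any configured damaging score past its
cutoff), hence monotone: adding annotation can only add variants.

Region percentages are paired with genome-footprint percentages computed
from the gene models over a configured non-masked genome length; that
length is a required input rather than something inferred, because masking
conventions differ between callers.

## The synthetic fixture generator

`generate_fixture()` is first-class, tested code, and the package's study
conditions live in its defaults: a 20 kb main contig plus a 5 kb contig
with no chain at all; an edit script with two deletions, an insertion and a
600 bp inversion (so every lift status arises, including minus-strand
chains); 1000 requested variants with a 12% indel share — the indel
fraction reported for real short-variant catalogs — at sites spaced ≥ 12 bp
so spans never collide; site frequencies from a neutral-like 1/f law on
(0.025, 0.95) (a uniform law and a 0.05-grid are available); a cohort of 16
founders and 8 trio offspring with genotypes drawn binomially from the
founders and transmitted to children, 2% missingness, and 5 planted
transmission violations; 8 planted allele swaps and 8 reference mismatches
made by editing the target sequence at lifted SNV sites; 30 clinical rows
(a spread of significance strings) plus 15 same-position different-allele
decoys; 40 positional scores against a 0.85 damaging cutoff; and 4 interval
tracks. Three genes are planted by writing designed coding sequences
(initiator, stop-free codons, terminator) into the source contig: a
plus-strand and a minus-strand two-exon coding gene and a non-coding gene.

The truth file is the generator's own bookkeeping, derived from the edit
script by direct segment arithmetic (not from the chain parser or the lift
engine), with consequences from a mutate-and-retranslate diff of the
planted coding sequences. Two things the truth shares with the package by
design: the normalization primitive (the expected target representation of
a reverse-strand indel is normalized like any other record) and the
initiator-first classification tie-break. Everything is a pure function of
the seed; identical specs give byte-identical bundles.

What the generator does *not* emulate: sequencing error and genotype
uncertainty, linkage between sites, population structure and relatedness
beyond the planted trios, realistic gene density, repeat-induced multi-
mapping, and real chain sets derived from whole-genome alignment. Passing
tests therefore demonstrate the correctness of the coordinate arithmetic,
the matching semantics and the bookkeeping — not calling accuracy on real
data, and not the lift rate any real chain set would achieve.

## Problem sizes and numerical choices

The shipped tests run the full pipeline at 250–1000 variants and the
determinism check at 10,000 variants over a 200 kb contig; the per-base
mapping oracle walks an 8 kb fixture exhaustively, and the consequence
oracle enumerates every SNV across a 300 bp CDS on both strands. These
sizes exercise every code path while keeping the whole suite in a few
minutes. There are no iterative numerical routines; all tolerances in
tests are exact equality on integers and exact identity on strings, with
floating frequencies compared at machine precision. Ties and degenerate
inputs are handled explicitly: empty cohorts summarize to zeros, variants
with no called genotype keep an undefined frequency rather than being
dropped, indels pinned at a contig start stop left-shifting and keep a
right anchor, and an empty annotation source list leaves only provenance
and consequence keys.

## Known limitations

Only `ACGT` alleles are processed; phasing is not preserved through
decomposition; sex chromosomes are not treated specially in the Mendelian
check (exclude them upstream if needed); HGVS output is a compact
`p.Xxx#Yyy` sketch, not full grammar; and multi-exon UTR structure is
inferred from exon-minus-CDS rather than annotated UTR features.
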