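---
title: "Rare reference allele detection: models, parameters and design choices"
author: "rrascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare reference allele detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why a dedicated caller

A resequencing pipeline reports differences between aligned reads and the
reference assembly. When the reference base at a locus is itself a rare
allele (population frequency under 1%), that design fails in both
directions: a sample homozygous for the reference base produces no variant
record at all, and in tumor/normal comparisons a reference allele private to
the tumor is subtracted away as germline signal. `rrascan` inverts the
perspective — it maintains a catalog of such rare-reference-allele (RRA)
loci and interrogates exactly those positions with a forced-allele
genotyper, so the presence of the *reference* allele becomes the reportable
event.

## The catalog model

Genotypes enter as non-reference dosage codes obtained from VCF GT fields
(0 = hom-ref, 1 = het, 2 = hom-alt; any non-reference allele counts toward
the dosage, so a 1/2 genotype codes as 2). With genotype counts
$n_{00}, n_{01}, n_{11}$ and missing genotypes excluded throughout,

$$\mathrm{AF}_{ref} = \frac{2\,n_{00} + n_{01}}{2\,(n_{00}+n_{01}+n_{11})}.$$

A locus enters the catalog when $\mathrm{AF}_{ref}$ is *strictly* below the
threshold (default 0.01; at a 1092-sample panel, 21 heterozygous carriers —
21/2184 ≈ 0.0096 — pass while 22 fail). Classes follow the genotype
configuration: **A** when no called genotype carries the reference allele,
**B** when it appears only in heterozygotes, **C** when both heterozygous
and homozygous-reference genotypes occur. The configuration "hom-ref
present, het absent" satisfies none of the three published definitions; we
assign it an explicit class **U** rather than silently folding it into C,
so the three-class partition remains faithful and U is visible downstream
(it is empirically absent from panels at this AF scale, where a hom-ref
carrier contributes two of at most 21 reference alleles).

Variant types are SNV/INS/DEL by allele length; equal-length multi-base
substitutions (MNVs) are rejected with an explicit error, since every
downstream rule (spans, GERP, pileup semantics) is defined only for the
three types. Multi-allelic records keep their full ALT list, but the first
ALT is the forced alternative allele downstream — forced genotyping with
more than one alternative allele is out of scope. Haploid GT values are
treated as missing by default; an option counts them as a single allele.

## Coordinates

Internally every interval is 0-based half-open; VCF positions are 1-based.
The conversion lives in one place (`vcf_span` and the readers in `R/io.R`).
Affected spans: an SNV covers its POS base; a deletion covers the deleted
bases with the VCF anchor base excluded; an insertion is anchored at the
insertion point and, for feature overlap, must fall *strictly* inside a
feature (both flanking bases contained) — a junction touching a feature
boundary is not an overlap.

## The forced-allele genotype likelihood model

At each catalog locus the pileup collects, per read, which of the two
supplied alleles it supports. SNV support is the aligned base at POS read
off the CIGAR; indel support is the presence or absence of the event in the
CIGAR at the locus junction, with the observation quality taken as the
minimum base quality over the event plus one flanking base — a deliberately
simple, testable observation model in place of realignment-based scoring.
Reads that do not span an indel event are uninformative and excluded.
Default read filters: duplicate, secondary, supplementary and unmapped
flags; mapping quality < 20; base quality < 13. Overlapping mates
contribute one observation (the higher base quality wins).

With per-read error $e = 10^{-Q/10}$:

$$P(\mathrm{obs}\mid a) = \begin{cases}1-e & \text{read supports } a\\
e/3 & \text{SNV otherwise}\\ e & \text{indel otherwise,}\end{cases}
\qquad
P(\mathrm{obs}\mid a_1/a_2) = \tfrac12 P(\mathrm{obs}\mid a_1) +
\tfrac12 P(\mathrm{obs}\mid a_2),$$

and genotype log10-likelihoods sum over reads. The posterior uses the
standard heterozygosity prior $(1-3\theta/2,\ \theta,\ \theta/2)$ with
$\theta = 0.001$. Exact posterior ties break toward the heterozygote — the
conservative direction for RRA filtering, since a heterozygote carries the
reference allele and stays visible to the germline filter.

The emitted site quality mirrors VCF QUAL under emit-all-sites semantics:
for a non-hom-ref call it is $-10\log_{10}P(\text{hom-ref}\mid D)$
(confidence that a non-reference allele segregates); for a hom-ref call it
is $-10\log_{10}(1 - P(\text{hom-ref}\mid D))$ (confidence that the site is
hom-ref). The two-sided form matters here: RRA analysis *keeps* hom-ref
calls, and a one-sided definition would leave them permanently below any
quality threshold. The germline retention threshold is QUAL ≥ 30, i.e. an
error rate below 0.1%. This package's likelihood model is specified above
in full and makes no claim of numerical parity with any external caller.

## Germline and somatic rules

Germline mode retains calls with QUAL ≥ 30 whose genotype contains at least
one reference allele, annotated with zygosity and catalog class; records
are filtered and annotated, never modified, so germline output is always a
subset of genotyper output. All reference-carrying calls are emitted with
their class labels (including hom-ref class-C calls), leaving downstream
filtering to the analyst.

Somatic mode evaluates matched pairs per locus on the *called genotypes*:
a candidate requires no reference allele in the normal and at least one in
the tumor; both calls must pass the quality threshold. Candidates are
tested with a Fisher exact test on the post-filter allele depths
$[[n_{ref}, n_{alt}], [t_{ref}, t_{alt}]]$, two-sided by default (the test
asks whether the allele composition differs, without presuming direction; a
one-sided flag exists), and a verdict requires $p < 0.01$. The Fisher
p-value is the probability-ordering sum of hypergeometric table
probabilities with the customary $1+10^{-7}$ relative tie tolerance; it is
implemented as a direct `dhyper` sum, which vectorizes over the exhaustive
table sweeps used in testing, and is cross-checked in the test suite against
both an independent `lchoose`-based enumeration and `stats::fisher.test`.
An all-zero table returns $p = 1$ by convention.

## Context metrics

"The 100 bp region surrounding each locus" is implemented as a window
centered on the locus base — the natural reading, though centering is not
the only one; the choice is documented and the width configurable. Even
widths place the extra base on the left. For multi-base indels the window
anchors on the VCF POS base. GC content divides G+C by called (non-N) bases
by default, with the total-length denominator available as an option.
Mean mappability averages per-base track scores over the window; bases
absent from the track contribute zero with a warning rather than shrinking
the denominator, so sparse tracks bias the estimate down visibly instead of
inflating it silently. Background windows are drawn uniformly over all
valid start positions, so per-contig counts are proportional to length.

## Annotation thresholds

GERP: SNVs and insertions pass when the RS score at the POS base is
strictly greater than 2; deletions pass when *any* deleted base does
(anchor excluded). The cutoff of 2 reflects the average constraint level of
coding exons. GAD disease classes count only records with a positive (Y)
association flag. OMIM membership is a gene-level join. The RegulomeDB
TF-binding flag is inclusive: score ≤ 3. Consequence classes are consumed
from a precomputed table (VEP-style output); re-deriving consequences is
out of scope, and the synthetic track generator plants a consequence table
so the end-to-end tests run with no external tools. Gene overlap counts any
transcript-span intersection (introns and UTRs included).

## The synthetic study

The generator's defaults are the study conditions: 1092 samples in four
macro populations at the source panel's proportions (AFR 246, AMR 181,
ASN 286, EUR 379); 100 loci — 20 class A, 40 class B, 10 class C, 30
non-RRA; class B plants 1–10 heterozygotes, class C 1–3 hom-ref plus 1–5
het carriers (both ranges keep AF under the 1% threshold by construction,
mirroring the ≤ 21-carrier arithmetic of the real panel); non-RRA loci get
Hardy–Weinberg genotype counts at AF ≥ 0.05. Reads are 100 bp at 40× with
uniform Q30 (30× for the genotype-recovery experiment), heterozygote reads
drawn allele-by-allele as a fair coin. Contigs total 50 kb with loci on a
300 bp grid, so read windows never interfere. These sizes keep the complete
test suite and the acceptance script to a couple of minutes while leaving
every planted event at unambiguous coverage.

What the simulation does *not* emulate — and what passing tests therefore
do not show about real data: realistic error profiles (qualities are
uniform; no context-dependent or strand-biased error), mapping ambiguity
(all reads are uniquely placed at MAPQ 60), contamination, tumor purity and
subclonality, indel realignment artifacts, and reference bias in alignment.
Recovery rates on synthetic data are upper bounds; on real alignments the
QUAL threshold and the Fisher test do the work the simulation makes easy.

## Numerical and degenerate-input choices

Likelihoods are accumulated in log10 space and normalized against the
maximum before exponentiation; posteriors are floored at $10^{-300}$ and
Phred values capped at 3000 to avoid infinities at high depth. A pileup
with zero observations yields a no-call record (emit-all-sites), which the
germline filter drops and the somatic comparator rejects with an explicit
reason. All-missing genotype records raise an undefined-AF error and are
skipped (with a count) during catalog construction; structural/symbolic
ALT records are skipped likewise. Catalog order is deterministic — chrom in
input order, then position, ref, alt — so outputs diff cleanly. Every
stochastic routine takes an explicit seed, saves and restores the caller's
RNG state, and produces byte-identical artifacts under the same seed.

## Known limitations

One alternative allele per locus record; no phasing; no structural
variants; no local realignment or haplotype assembly; coordinate remapping
between assemblies is consumed as a table, not computed; germline samples
are filtered independently (no joint multi-sample re-calling). The
full-scale catalog of the published panels requires the original multi-gigabyte
downloads and is out of desk-scale reach by design; the package's
guarantees are established on the planted-truth synthetic study instead.
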