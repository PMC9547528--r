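---
title: "Subgenome fractionation and chromatin environment: models and methods"
author: "subfrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome fractionation and chromatin environment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

After a whole-genome duplication (WGD), the two resulting subgenomes of a
paleopolyploid rarely evolve symmetrically.  In maize, the dominant
subgenome (maize1) has retained more genes than the recessive subgenome
(maize2) — *biased fractionation* — and its surviving homoeologs tend to be
expressed more highly, evolve under stronger purifying selection, sit
farther from transposable elements (TEs), carry fewer flanking 24-nt
siRNAs and less CHH methylation, and keep more of their accessible
chromatin regions (ACRs).  A central question is how much of this bias
depends on *chromatin environment*: gene-rich, recombinogenic chromosomal
arms versus TE-rich, recombination-suppressed pericentromeres.

`subfrac` implements that comparison as a reusable pipeline:

1. **partition** — segment each chromosome into two arms and one
   pericentromeric region from windowed gene density, repeat content and
   recombination rate;
2. **fractionation** — filter syntelog tables, classify retained
   pairs/singletons, assign the four chromatin-environment categories
   (M1arm–M2arm, M1peri–M2peri, M1arm–M2peri, M1peri–M2arm), build
   duplicated block pairs and their summary statistics;
3. **molevol** — Ka/Ks/ω by Nei–Gojobori (1986) codon counting,
   Jukes–Cantor K for non-coding ACR sequence, and GERP-based genetic
   load;
4. **dominance** — the per-tissue two-fold "horse race" expression
   classifier and paired mean-expression tests;
5. **profiles** — strand-aware metagene profiles of TE proportion,
   24-nt siRNA abundance (TP10M), weighted DNA methylation and histone
   ChIP signal;
6. **acr** — genic/proximal/distal ACR classes, subgenome retention
   ratios, the five syntenic-ACR retention categories, accessibility
   comparisons and chromatin-loop counts;
7. **synthetic data** — a parameterised two-subgenome genome generator
   that makes every stage testable end to end.

## Genome partitioning

Gene density (genes/Mb) and repeat length (Mb/Mb) are measured in 1 Mb
windows advancing by 500 kb; recombination rates (cM/Mb) are piecewise
slopes between consecutive genetic markers, and a position inherits the
rate of its enclosing marker interval.  Studies of this kind usually draw
the arm/pericentromere boundaries *manually* from these tracks.  We
automate the rule: the pericentromeric region is the maximal contiguous
run of windows containing the centromere in which the smoothed (5-window
running mean) recombination rate is below `rMax` (default 1 cM/Mb) **and**
the repeat fraction exceeds `tMin` (default: the per-chromosome median).
`segmentGenome()` also accepts explicit boundaries, so an externally
(e.g. manually) defined partition can be reproduced exactly.  These
defaults are calibration choices — the manual procedure they replace was
never stated numerically — and both thresholds are exposed as arguments.

Boundary features are classified by their midpoint, giving each gene and
ACR a single unambiguous label, as the category scheme requires.  Genes
are counted into windows by start position so overlapping windows never
double-count within a window.

## Evolutionary distances

Ka and Ks are computed by NG86-style counting on pairwise codon
alignments: synonymous site fractions per codon (averaged over the two
sequences), equal-weight averaging over all substitution pathways in
multi-difference codons, and the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ applied to $p_S = S_d/S$ and
$p_N = N_d/N$.  Conventions the counting needs but the literature leaves
open are fixed as follows: mutations *to* stop codons count as
nonsynonymous in site counting (so each codon contributes exactly three
sites), substitution pathways passing *through* a stop codon are excluded
from the average (all pathways are used if every one is blocked), and any
codon containing a gap or non-ACGT character in either sequence is
skipped entirely.  In-frame stops are rejected — alignment-induced stops
must be masked to gaps beforehand.  $p \ge 0.75$ raises a saturation
error rather than returning a complex number.

This is a deliberate re-implementation, not a wrapper around `yn00`: the
package's counting is verified against an independent brute-force
pathway-enumeration oracle to $10^{-9}$ and by parameter recovery on
synthetic alignments, and will not numerically equal codeml-family
maximum-likelihood estimates.  ACR divergence uses plain Jukes–Cantor
(JC69) on aligned non-coding sequence — the simplest defensible model for
short non-coding fragments; a different `baseml`-style model would shift
K values slightly but not the subgenome contrasts.

Genetic load follows the standard GERP-based recipe: deleterious loci are
nonsynonymous SNPs with GERP score strictly greater than 0; the load is
the panel-averaged count of derived alleles at those loci divided by the
gene-body length in bp.

## Expression dominance

In each tissue, a homoeolog "wins the horse" when its expression is
two-fold or greater than its partner's (ties at exactly the threshold
count as a win).  Because $2 \times 0 = 0$ would make a (0, 0) pair
"dominant" in both directions, the winner must additionally reach
`minExpr` (default 1 FPKM; configurable, and set to 0 in tests that need
the pure ratio rule).  Percentages are reported over **all** pairs of a
category in that tissue — the natural denominator when comparing
categories; restricting to expressed pairs is a one-line filter upstream.
Paired t-tests on per-pair mean FPKM are reported on the raw scale and on
log2(x+1), since either convention appears in this literature.  Protein
abundance matrices run through the identical classifier.

## Metagene profiles

All profiles are strand-aware (upstream = 5′ of the TSS, downstream = 3′
of the TTS) over 2 kb flanks:

* TE proportion and 24-nt siRNAs: 100 bp windows sliding by 10 bp, hence
  $(2000-100)/10+1 = 191$ windows per side.  siRNA counts are normalised
  to TP10M ($c \cdot 10^7 / \text{library}$).
* DNA methylation: *weighted* methylation (summed methylated calls over
  summed total calls) in 50 bp non-overlapping windows; windows without
  covered cytosines are excluded from cross-gene means rather than
  treated as zero, because the weighted level is undefined there.
* Gene bodies: 40 equal-size bins, bin size varying with gene length;
  genes shorter than 40 bp are skipped with a warning.
* Histone ChIP: $\log_2((\text{treat}+1)/(\text{input}+1))$ in 100 bp
  windows across flanks and body.

Flanks are truncated (not discarded) at chromosome ends, and per-window
gene counts are tracked so means always use correct denominators.
Cross-gene averaging uses per-gene window values (not pooled counts);
pooling would weight genes by coverage, which is undesirable when
libraries differ between loci.

## ACRs and loops

ACRs are classified against their nearest gene by edge-to-edge distance:
genic (any overlap), proximal (within 2 kb, boundary inclusive), distal
(beyond 2 kb).  ACRs whose nearest gene has no outgroup syntelog are
excluded from retention ratios, mirroring the filtering used for genes.
Because sequence-similarity thresholds for calling ACR homology are not a
settled standard, homology is an *input* table (the synthetic generator
emits ground truth), from which the five retention categories follow:
near WGD genes — (1) both copies retained, (2) maize1 only, (3) maize2
only; near singletons — (4) maize1 only, (5) maize2 only.  Chromatin
loops are assigned by the partition classes of their two anchor
midpoints; loops whose anchors disagree get a separate `mixed` label and
stay out of per-region comparisons.

## Shared statistics

Contingency comparisons use Pearson's χ² without continuity correction
(counts are in the thousands; the correction is immaterial and can be
switched on).  Paired comparisons use Student's paired t with the two
degenerate cases made explicit (all-zero differences → P = 1; constant
non-zero differences → P = 0).  The report keeps raw P-values — matching
the practice of the studies this package models — and can append
Benjamini–Hochberg q-values, clearly labelled as an extension.

## The synthetic generator

`generateDataset()` writes a complete toy two-subgenome dataset — GFF3
genes, BED TEs, marker map, syntelog table, ancestral ("sorghum-like")
and evolved CDS FASTA, FPKM/protein matrices, SNP+GERP table with a
genotype panel, siRNA/methylation/histone tracks, scored ACR BED, ACR
homology, loops, and a ground-truth JSON.  Identical config + seed gives
byte-identical files.

Its default parameters are the package's study conditions: 3 chromosomes
of 15 Mb per subgenome; 40% pericentromere; gene densities 75/25 per Mb
(arm/peri), giving ≈2,500 ancestral genes and 600–700 retained pairs; TE
fractions 0.2/0.6; 24 expression tissues.  Where a published quantity
pins a parameter we derived it once from the printed values: the
mutually exclusive copy-loss probabilities (m1 arm 0.19 / peri 0.24, m2
arm 0.50 / peri 0.55) come from the singleton:WGD ratios
1.7/2.2/0.7/0.9 combined with the pair-category proportions
(2877/429/720/552) as partner-region mixture weights.  Two structural
choices matter for realism: maize2 pericentromeres are shifted by 0.12 of
the chromosome length to mimic post-WGD rearrangement (creating all four
chromatin-environment categories), and each maize2 block is placed at the
same relative bp span as its maize1 block, because synteny preserves
large-scale position and that positional correlation is what produces the
region-dependent ratio pattern.

The sequence model draws ancestral CDS uniformly over sense codons and
applies Poisson numbers of synonymous and nonsynonymous single-nucleotide
substitutions at the configured per-site rates, never creating in-frame
stops, so evolved and ancestral sequences are equal-length, gap-free and
already aligned.  The expression model is a pair-shared log-normal
baseline with per-tissue effects shared by both copies, a multiplicative
dominance factor applied to the maize1 copy of an exact fraction of
arm-located pairs, and per-copy log-normal noise.  Flanking siRNA/CHH
"islands" are Gaussian bumps centred 500 bp outside the TSS and TTS
(maize2 scaled 1.3×); methylation carries per-cytosine
methylated/total calls at 20 bp spacing, histone tracks 100 bp binned
treat/input counts.

What the generator does **not** emulate: realistic TE taxonomy or
nesting, read-level data (tracks are count-level), indels or alignment
error, tandem arrays beyond a flag, linkage disequilibrium in the SNP
panel, and fine-scale recombination variation.  Passing tests therefore
demonstrate that the implementations compute their defined quantities
and recover planted biases — not that the biological conclusions would
survive the messiness of real sequencing data.

## Problem sizes and numerical choices

The test suite runs the full pipeline on a reduced genome (2 × 10 Mb
chromosomes per subgenome, ≈250 pairs) and the acceptance script on the
default study conditions (3 × 15 Mb, ≈650 pairs); both finish in a few
minutes on one CPU.  Monte-Carlo parameter recovery uses 100 replicate
300-codon pairs with a 3-standard-error band.  Ratios are reported
rounded to one decimal in the field's `x.y:1` convention with raw counts
always preserved; all internal comparisons use the unrounded values.

## Known limitations

* NG86 with equal-weight pathways is a counting estimator; for deeply
  diverged pairs a maximum-likelihood codon model would be preferable.
* Automated segmentation reproduces a manual partition only to window
  resolution (±1 Mb at the defaults); supply explicit boundaries to match
  a published partition exactly.
* Block construction assumes syntelog tables ordered by an outgroup gene
  order and defines blocks as maximal runs on a shared chromosome
  pairing; externally defined block boundaries can be loaded instead.
* The dominance classifier is deliberately threshold-based (two-fold);
  it is not a statistical test of differential expression.
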