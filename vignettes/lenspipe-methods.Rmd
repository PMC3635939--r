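---
title: "Methods: models, parameters and design choices in lenspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lenspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenspipe)
```

lenspipe implements the computational stages of a 3′-cDNA transcriptome
SNP resource for an inbred crop panel: read-depth-threshold SNP calling
against reference contigs, codon-impact annotation, synonymous
divergence (Ks) dating, genotyping-array candidate selection, RIL
linkage-map construction, and synteny chaining against a model genome.
This vignette records the models behind each stage, the parameters that
matter, and the choices made where the design was genuinely open. No
empirical claim is made here beyond what the package's tests and the
acceptance script themselves compute.

## SNP calling and the non-redundant merge

A pileup row is `(contig, pos, depth, A, C, G, T)` with counts summing
to depth. For one genotype, the most frequent non-reference base at a
site is a **confident alternate call** iff it is supported by at least
`min_reads = 3` reads *and* at least `min_fraction = 0.8` of all reads
at the site. Both boundaries are inclusive — the failing set is "below
80% or below 3 reads" — so 8 alternate reads out of 10, or 3 of 3, pass.
The fraction is computed over all reads at the site, not over
reference-plus-alternate reads only; with error-free data the two
denominators coincide. Sites failing either rule but showing at least
one non-reference read are **below-threshold**; zero-depth sites are
**missing**. Heterozygous genotypes are not modelled: the panel lines
are inbred, and calls are reference / alternate / no-data.

The merge creates one record per `(contig, pos, alt)` that is confident
in at least one genotype, then assigns every other genotype `ALT`,
`REF`, `BELOW_THRESHOLD`, or `MISSING` at that record. Below-threshold
evidence is only ever *reported* at positions confident somewhere — a
position that is below-threshold in every genotype produces no record.
Two design points needed a decision:

* **Multi-allelic sites.** Two genotypes confident for different
  alternate bases yield two biallelic records and a logged warning. On
  each record, a genotype whose non-reference evidence does not match
  the record's alternate (including a confident call for the *other*
  alternate) is marked `BELOW_THRESHOLD`: it is demonstrably not
  reference, and not this record's alternate, and this conservative
  marking keeps it out of allele-frequency denominators.
* **Allele frequencies.** Per record, frequency = confident-ALT
  genotypes / informative genotypes (`REF` or `ALT`), with the reference
  genotype counted as one additional `REF` by default
  (`include_reference = TRUE`, switchable); the summary is the
  unweighted mean over records with at least one informative genotype.

Monotonicity (relaxing either threshold can only grow the confident
set), row-order invariance, and exact agreement with a brute-force
evaluation of the rule are covered by tests.

## Gene anchoring, regions and codon impact

Anchors map a contig onto a model gene: strand, CDS and 3′-UTR intervals
in contig coordinates, exon-junction positions, and a model-genome
chromosome/position with an aligned-length × identity weight. They are
read from GFF3 or computed by a deliberately simple exact-seed/ungapped
extension anchorer that is adequate for synthetic and low-divergence
data; cross-species anchoring of real data should come from a dedicated
spliced aligner, and the package consumes its output as precomputed
anchors.

A SNP inside a CDS interval is exonic; inside the annotated 3′-UTR,
`UTR3`; anything else — including 5′-UTR, which 3′-anchored data barely
samples — is `UNASSIGNED`. For exonic SNPs the codon is extracted
strand-correctly (the contig and alleles are reverse-complemented for
minus-strand anchors, so a reverse-strand anchor gives the identical
impact as the equivalent forward construction; an involution test checks
this) and the change graded:

* `SYNONYMOUS` — same amino acid, neither a stop;
* `STOP_GAIN` — the alternate codon is a stop (overrides the
  non-synonymous classes, which keeps the four classes a partition);
* `NONSYN_SAME_PROP` / `NONSYN_DIFF_PROP` — different amino acid with
  the same / a different physico-chemical group.

The property grouping — acidic {D,E}, basic {K,R,H}, polar uncharged
{S,T,N,Q,C,Y}, nonpolar {A,V,L,I,M,F,W,G,P} — is a documented default
passed as an argument, not a constant; only the basic-vs-acidic contrast
is canonical, and users with a different grouping can supply it.
Reference stop codons (stop-loss or stop-retained changes) fall outside
the four classes and return `NA`; in the generator only the terminal CDS
codon is a stop, so this is rare by construction. All 9 × 61 = 549
single-base changes of sense codons are checked against an independent
enumeration oracle.

## Ks estimation and divergence dating

Only equal-length, gap- and N-free coding alignments are accepted — the
package does not realign; "indel-free pairs only" is itself the
upstream filter for this analysis. Nei–Gojobori (1986) counting is used:
per codon, each position contributes the fraction of its three possible
changes that are synonymous (changes creating a stop count as
non-synonymous), summed to S per sequence and averaged across the two
sequences; codon differences at two or three positions are averaged over
all mutational pathways, excluding pathways through stop codons when any
pathway avoids them. With `pS = Sd/S`, the Jukes–Cantor correction gives
`Ks = -(3/4)·ln(1 - (4/3)·pS)`. NG86 is a deliberate, documented
substitute for maximum-likelihood codon models: at the low divergences
relevant here it tracks ML closely, is deterministic, and needs no
external dependency. At `pS ≥ 0.75` the correction saturates; the
estimate is returned with `Ks = NA` and a `saturated` flag (with a
warning) rather than an error, because even a single-codon comparison
must be representable; `divergence_time()` then refuses the non-finite
input.

The population estimate is the **mode of binned Ks values**: fixed-width
bins anchored at 0 (`bin_width = 0.01`), midpoint of the most populated
bin, ties to the lowest bin. Dating uses the standard identity
`T = Ks/(2r)` with `r = 5.17e-3` substitutions per synonymous site per
Myr (the legume-lineage rate). Note that this identity applied to a mode
Ks of 0.07 gives 6.77 Myr.

Two numerical limits are worth stating. First, the binned mode
quantizes: the midpoint can be off by up to half a bin, so at
`bin_width = 0.01` divergences below roughly 2.5 Myr (Ks < 0.025) carry
more than 20% quantization error regardless of sample size, and the
recovery tests therefore cover 5–40 Myr. Second, NG86 with pathway
averaging undercounts slightly at moderate divergence (about 5% at
Ks ≈ 0.05 in the generator's own simulations); the recovered time for a
planted 5 Myr split is typically 4.35 Myr with 500 pairs of 200 codons,
within the 15% band the tests require.

The pair generator plants synonymous events per codon as a Poisson draw
with mean `2rT · s(codon)` applied through single-base synonymous
neighbours (never through stops), plus non-synonymous events at
one-tenth that per-site rate, so the planted density is recoverable by
the same counting it is tested with, up to multiple-hit effects.

## Array candidate selection

Filters follow assay-design practice for fixed-content arrays:

1. **Cultivated polymorphism** — keep SNPs with a confident alternate in
   at least two cultivated genotypes versus the reference; wild-only
   variants are removed.
2. **Flank cleanliness** — at least 60 bp on each side to the nearest
   contig end, other recorded SNP, or splice site. Exactly 60 bp passes
   (the rule eliminates "less than 60 bp"). Distances to *all* recorded
   SNPs count, including below-threshold ones — the stricter reading —
   because an interfering polymorphism disturbs hybridisation whether or
   not it was confidently called; passing a filtered table relaxes this.
3. **Haplotype deduplication** — one SNP per predicted haplotype per
   contig, where the haplotype is operationalised as the exact
   per-genotype status vector; duplicated contig pairs contribute at
   most one assay.
4. **External design scores**, when supplied, are opaque numbers in
   [0,1]: scores ≤ 0.4 are excluded and scores > 0.6 preferred. The
   package never computes them.
5. **Even genome spread** — greedy farthest-point thinning on a
   concatenated model-genome coordinate, high-score tier first,
   initialised at the smallest coordinate, ties broken lexicographically
   by SNP id, so selection is deterministic given the input. "Even
   spread" is a stated goal, not an algorithm, in array-design practice;
   farthest-point selection is this package's concrete choice, and a
   test checks the selected set's median nearest-neighbour spacing beats
   random subsets.

KASP-style flanks are emitted as `LEFT[REF/ALT]RIGHT` with 60 bp
windows, truncation at contig ends flagged, and a parser inverts the
format exactly.

## RIL simulation and linkage mapping

The simulated population mirrors an F8 RIL design: parents are opposite
homozygotes everywhere, and the F1 is selfed exactly
`selfing_generations = 7` times rather than assuming fully inbred lines,
so residual heterozygosity is ~`0.5^7 ≈ 0.8%` and is visible in the
calls. Gametes follow a crossover Markov chain along each linkage group
with adjacent-interval recombination fractions from the inverse Kosambi
function and **no interference** — the simplest process consistent with
the Kosambi distances used downstream (the mapping function allows
partial interference in the distance scale even though crossovers are
placed independently). Calls are `A/B/H/U`; a configurable handful of
"poor DNA" individuals (default 5 of 147) get an elevated missing rate
so that the pre-mapping QC step, which drops individuals above a
missing-fraction threshold (default outcome: 139 retained), has
something realistic to do. The QC cutoff is a parameter because only the
outcome, not the threshold, is ever reported in practice.

Mapping statistics, for markers with homozygous calls at both loci
(`H` and `U` are uninformative — residual heterozygotes carry ambiguous
recombination information in selfing RILs):

* observed recombinant fraction `R = k/n`;
* per-meiosis fraction via the Haldane–Waddington selfing-RIL identity
  `R = 2r/(1+2r)`, inverted to `r = R/(2(1-R))`, capped at 0.5;
* `LOD = k·log10(R/0.5) + (n-k)·log10((1-R)/0.5)` (so 20 identical
  informative calls give LOD ≈ 6.02);
* groups = connected components of the LOD ≥ 6 graph. Raising the
  threshold can only refine the partition, never merge groups.

Marker ordering is a documented heuristic, not a reimplementation of
maximum-likelihood/regression map ordering: a greedy nearest-neighbour
walk through the `r` matrix (started at the marker with the largest
distance sum, a likely terminus) refined by 2-opt on the sum of adjacent
`r`, distances `kosambi_cM(r)` accumulated from 0, orientation
canonicalised so group reversal changes nothing. Its validation is
simulation recovery: on 139 simulated RILs with 7 × 70 markers the true
partition is recovered exactly and per-group order correlates with truth
at |Spearman ρ| ≥ 0.95 (in practice ≈ 1.0). Because `r` is estimated
from finite recombinants with missing data, total map length comes back
within a few percent of, typically slightly below, the simulated truth;
no printed map length is used as a target.

## Synteny chaining

Anchors carry `(marker, lg, cM, model_chrom, model_pos, align_len,
identity)` with weight = aligned length × identity. Per linkage group ×
chromosome pair, the **weighted longest increasing subset** is the
maximum-total-weight subset whose model positions are strictly
increasing (forward) or strictly decreasing (inverted) in cM order,
solved by the O(n²) DP with deterministic earliest-cM tie-breaks; on
instances of up to 12 anchors it is checked against exhaustive search
over all 2ⁿ subsets, and a reflection symmetry (forward on mirrored
coordinates = inverted on originals) is tested.

Block calling runs the LIS in the heavier orientation, re-chains the
leftovers in the opposite orientation, sorts the union by cM, and
segments it into maximal constant-direction runs (an anchor at a
direction change belongs to both flanking runs); runs of at least
`min_block = 3` anchors become blocks. A block whose orientation is the
weight-minority within its linkage group is flagged as an **inversion**
— a wholly reversed group is an orientation convention, not a
rearrangement, so single-orientation groups are never flagged. A group
with `min_block`-plus anchors in blocks on two or more chromosomes is
flagged as a **translocation**. `min_block = 3` and the planted-event
window of 6 anchors in the generator are package choices: three anchors
is the smallest run distinguishable from noise, and six-anchor events
are modest "major" rearrangements at the anchor densities simulated.
Chaining per chromosome pair (rather than one global chain) matches
delta-filter-style practice; the alternative is noted but not
implemented.

## The synthetic-data generator: scope and honesty

The generator emulates the *statistical structure* the pipeline needs:
contigs of gamma-distributed length (mean 600 bp, min 200) that are a
sense CDS closed by a stop plus a 3′-UTR (`utr3_fraction = 0.3`);
planted maximal SSRs (5% of contigs) with guard bases so truth tracts
are exactly maximal; ~1% near-identical duplicate contigs; 20% of
contigs stored antisense to exercise strand handling; exon junctions as
annotation (the cDNA itself is contiguous); and a collinear model-genome
anchor per contig with optional planted rearrangements. The panel is 1
reference + 8 cultivated + 2 wild genotypes: cultivated variants are
standing variation drawn from a shared pool whose carrier counts follow
the neutral site-frequency spectrum (P(k) ∝ 1/k), scaled so each line's
expected divergence from the reference is `theta_cultivated = 0.002`;
wild divergence (`theta_wild = 0.01`) is placed mostly
(`wild_shared = 0.7`) on a species branch shared by both wild
accessions. This reproduces the qualitative contrasts that drive the
downstream stages — wild lines carry several-fold more variants, shared
wild variants raise the all-lines allele frequency above the
cultivated-only average, and enough variants are polymorphic among
cultivated lines to feed array design. The divergence levels themselves
are calibration knobs, not estimates of any real panel. Depths are
Poisson per site around per-genotype means (the study design's 8–31×
range), with a symmetric per-read miscall probability.

What it deliberately does **not** emulate: indels (the pipeline ignores
them by design), 454 homopolymer errors, assembly artefacts beyond
simple duplicates, base-composition bias, paralog gene families,
linkage between variant sites, or segregation distortion. Passing tests
on this generator therefore demonstrates correctness of the
*computations* under clean, known-truth conditions — recall/precision of
the calling rule, recovery of planted maps and rearrangements — not
robustness to real 454 noise or assembly error.

## Problem sizes and numerical conventions

The analysis drivers and acceptance script use: 300 contigs (~190 kb;
~3,400 planted variants), error rate 0.002; 500 CDS pairs of 200 codons
for dating; 139–147 RILs × 490 markers for mapping; 7 × 30 synteny
anchors; 200 random ≤ 12-anchor instances for the LIS oracle. These
sizes give stable statistics while keeping every stage interactive.
Conventions collected in one place: internal coordinates are 1-based
inclusive in all R structures, and emitted files use their standards'
conventions (GFF3/VCF/pileup 1-based); seeded generators save and
restore the caller's RNG state; histogram ties go to the lowest bin;
selection and chaining ties break lexicographically (SNP id) or by
earliest cM; the 60 bp flank boundary and the 80%/3-read thresholds are
inclusive on the passing side; degenerate inputs (empty contig sets,
all-missing individuals, saturated pS, markers without map positions)
raise typed errors or flagged NA values rather than propagating
nonsense.
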