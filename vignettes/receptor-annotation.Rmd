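---
title: "Annotating divergent receptor gene families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating divergent receptor gene families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rscout)
```

This vignette documents the models, parameters and design decisions behind
`rscout`, in the spirit of a methods section: what each stage assumes, which
knobs matter, what the synthetic validation does and does not demonstrate.

## The annotation problem

Odorant-receptor (OR) and ionotropic-receptor (IR) families in insect
genomes combine every annoyance a gene annotator can meet at once: deep
divergence (often < 50 % amino-acid identity to the nearest annotated
homolog), multi-exon structures with phase-shifted introns, a high
pseudogenization rate driven by frameshift indels, draft assemblies whose
short contigs duplicate loci as allelic variants, and genuine tandem arrays
of recent paralogs that superficially look like the same problem. The
pipeline mirrors the manual workflow used for such families — translated
homology search, hand assembly of exons, splice-site refinement, and a set
of explicit curation rules — but as deterministic, parameterized code.

## Translated search

`find_exon_hits()` is a desk-scale stand-in for tblastn. Scaffolds are
translated in all six frames (N-containing codons become X, stops `*`);
seeds are exact shared 3-mers whose BLOSUM62 self-score reaches
`seed_score_min = 11`, and a diagonal is only extended when two seeds
co-occur within `two_hit_window = 40` residues (the classic two-hit
heuristic; for queries shorter than twice the window a single seed
suffices, so tiny exact queries still report). Extension is ungapped with
X-drop termination (`x_drop = 20` raw units) and never crosses a stop
codon: each hit is a candidate *exon*, and bridging introns is deliberately
left to the chainer. Finally hit ends are trimmed while the terminal
8-residue window holds under 50 % identities — X-drop extensions otherwise
wander a few lucky codons into flanking introns, which would inflate query
overlaps between neighboring exon hits.

Raw-score reporting (`score_min = 50`) replaces E-value statistics: on
genomes of a few megabases Karlin–Altschul calibration buys nothing, and a
raw threshold keeps every decision reproducible. Gapped within-exon
alignment is not attempted; at the substitution rates the curation rules
are specified for (a few percent) exons are gap-free, and larger indels are
precisely what the lesion detectors downstream must see, not absorb.

## Chaining and splice refinement

`chain_exons()` solves weighted colinear chaining by dynamic programming:
chained hits share a strand, advance in genomic and query coordinates,
bridge at most `max_intron = 10,000` nt, and may overlap on the query by at
most `max_query_overlap = 15` aa. Ties break to the leftmost genomic start;
chains are extracted greedily by score, retiring everything inside an
accepted chain's span, so one locus yields one chain per query.

`refine_splice_sites()` turns a chain into a gene model. For each adjacent
exon pair it enumerates donor GTs and acceptor AGs within ±15 nt of the raw
hit boundaries (widened by three nucleotides per residue of query overlap
or gap), subject to two hard constraints: the split-codon phases must sum
to a full codon — phase arithmetic is anchored on the *original hit codon
grids*, because refined acceptors acquire partial codons — and the implied
intron must be at least `min_intron = 40` nt. The candidate pair maximizing
the ungapped BLOSUM62 score of the translated junction (ten codons of
context each side) wins; ties break by distance to the raw boundaries, then
leftmost donor, then leftmost acceptor.

The minimum-intron constraint doubles as the frameshift detector: the two
sub-hits flanking a 1-nt deletion sit a few nucleotides apart, no
admissible GT–AG pair exists, the junction keeps its raw boundaries and
sets `frame_break`. Junctions spanning a run of ≥ 20 N instead become *gap
junctions*: the model bridges them with an N-placeholder exon sized to the
missing query block, so the deduced protein carries an X run (the signature
of a missing internal exon) without faking a splice. When a junction fails
and a flanking hit has identity below `min_hit_identity = 0.75`, that hit
is treated as spurious and dropped from the chain — random hits
occasionally chain onto real genes, and a junction that cannot be spliced
against a low-identity neighbor is evidence of exactly that.

Terminal exons are extended codon-by-codon to cover the query ends (only
when the terminal hit's identity clears the same 0.75 bar, so junk chains
are not inflated into full-length "proteins"), clamped at scaffold edges;
a following in-frame stop codon is absorbed into the last exon.

## Lesion flags and status classification

`translate_model()` finalizes per-model flags: `internal_stop` (a stop
before the terminal codon), `has_internal_N`, terminal-codon presence, and
`frame_break`. Besides the junction-level signal, a frame break is called
from alignment: the three frame translations of the CDS are locally aligned
to the reference, and a second frame that scores ≥ 55 over ≥ 20 residues
and explains ≥ 25 reference residues the best frame does not is the
signature of an indel of length ≢ 0 (mod 3).

`classify_status()` is a total function with pseudogene precedence:
`internal_stop || frame_break` → pseudogene; then missing 5′ (no start
codon, or ≥ 20 unmatched reference N-terminal residues under global
alignment), missing 3′ analogously, both → `partial_NC`; internal N runs or
an unmatched internal reference block ≥ 30 aa → `partial_M`; else complete
when reference coverage ≥ 0.8. A model failing the coverage bar with no
localized missing block falls back to `partial_M` (scattered unaligned
reference material is, operationally, missing internal sequence).
Fragments are discarded before classification: deduced proteins shorter
than 150 aa — judged on the *full* reading-frame translation, so pseudogene
models are not measured by their pre-stop prefix — are probable gene
fragments.

## Alleles versus paralogs, and naming

Draft assemblies place allelic variants of one locus on separate short
contigs. For every model pair with global CDS nucleotide identity ≥ 0.95:
if the alignment contains only substitutions and gaps of length divisible
by three, and exactly one member sits on a contig < 10,000 nt, that member
is excluded as a likely allelic variant. Pairs on one scaffold are tandem
paralogs and both are kept regardless of identity. Everything else is kept
and logged. The 10-kb bound is the scale at which short contigs stop being
able to carry independent loci of these ~2–5 kb genes with flanks; 0.95 is
deliberately above the nucleotide divergence of recent paralog pairs.

Naming inherits the reference numbering where the evidence supports
orthology: a model gets its best reference's number only when the two are
reciprocal best matches (checked against the full model×reference identity
matrix). Everything else receives the smallest unused integers in genomic
order, and the completeness suffix (N/C/NC/M/P) is appended for reporting.

## Identity and catalog statistics

`pairwise_identity()` uses Needleman–Wunsch global alignment (BLOSUM62, gap
open 10 / extend 0.5) and divides identical columns by *all* alignment
columns, gaps included. Published catalogs rarely state their identity
denominator; this choice is pinned, and `denom = "aligned"` /
`denom = "shorter"` are selectable for comparison on new data. Threshold
counts in `summarize_catalog()` use strict inequality ("higher than 50 %").
The bundled OR/IR table fixtures are transcribed as printed and checksummed
in the tests; a known internal inconsistency of the source tables (a
text/table disagreement on the complete-gene count, which also affects the
printed intact-gene mean identity) is documented in
`inst/extdata/table_fixture_notes.md` and deliberately not "corrected".

## Intron conservation

Splice sites convert to protein coordinates by the convention that an
intron after `c` coding nucleotides sits at amino acid `⌊c/3⌋ + 1` with
phase `c mod 3`; the synthetic implanter uses the exact inverse, so the
round trip is testable. Marks project through a protein MSA (column of the
residue, counting non-gaps per row) and scale to a common 400-aa axis by
half-up rounding of `column / alignment_length × 400`, clamped to [1, 400]
— the alignment length, not each protein's own length, so every gene shares
one axis. Junctions flanking N-placeholder exons are skipped: they are
assembly artifacts, not splice sites.

Nearby scaled positions (within `merge_radius = 1`) merge onto the position
with the largest pooled gene count — the parsimony reading that adjacent
marks are one ancestral intron seen through alignment jitter; merging is
selectable off. A merged position is conserved within a species at
`min_genes = 8` (a "more than 8" phrasing elsewhere counts 8-gene sites as
conserved, so ≥ 8 is the consistent reading, flagged as an interpretation),
and conserved across species when conserved in every set. Phase is reported
but ignored in merging, matching the phase-free common axis.

## Phylogeny

Pairwise distances are maximum-likelihood estimates under the JTT model:
the published exchangeabilities and stationary frequencies are
eigendecomposed once (scaled to one expected substitution per site per unit
time), and for each pair the likelihood of its site-pattern counts over
shared non-gap columns is maximized over t by scalar optimization
(tolerance 1e-8, saturation cap 10 substitutions/site). Identical rows
return exactly 0. The tests cross-check this against both a brute-force
likelihood scan on a 1e-4 grid and an independent implementation. The
original analysis used an ML-framework distance tree in a GUI package; NJ
on pairwise-ML JTT distances is the deterministic, scriptable equivalent,
and on additive matrices NJ is exact (also a test).

Bootstrap supports resample alignment columns with replacement,
deterministically for a seed, and count bipartition recovery on the
original NJ tree. Ortholog subgroups are read from the rooted
representation of a species-labeled tree as the *smallest* supported clades
(default ≥ 70 %) containing at least two species — nesting a subgroup
inside a bigger mixed clade would double-count — and species-specific
clades are the maximal supported single-species clades not inside a called
subgroup. Nodes without a support value (the root) pass the support check.
Rooting changes what is a clade: callers comparing against a published
rooted tree should root on the appropriate outgroup (e.g. the Orco clade
for OR trees) first.

## Protein features

TM counting is a transparent hydropathy scan, not an HMM topology model:
Kyte–Doolittle window means (window 19, threshold 1.6), qualifying window
*centers* pooled into segments, segments ≤ 5 aa apart merged. It serves the
pipeline role of flagging models that lack the 7-TM hallmark; divergence
from a real topology predictor on real proteins is expected, and TM counts
are reported, never used as a filter. Proteins shorter than one window
return zero segments with a warning.

IR domain annotation is alignment transfer from a bundled *synthetic*
annotated reference (`make_ir_reference()`, also shipped as
`inst/extdata/ir_reference_synthetic.*`): S1/S2/pore intervals and the
three diagnostic ligand-binding positions (S1 arginine, S2 threonine,
S2-end aspartate/glutamate) at fixed coordinates in a deterministic
500-aa sequence. A domain is absent when more than half its reference
columns align to gaps; key-residue flags read the aligned column and are
FALSE-with-gap-note when deleted. The reference is a test harness for the
transfer machinery — real analyses should substitute a genuinely annotated
iGluR.

## Expression

`delta_delta_ct()` implements the standard 2^−ΔΔCt quantification:
technical replicates averaged on the Ct scale, ΔCt against the reference
gene per sample, ΔΔCt against the calibrator sample, no efficiency
correction. The calibrator is always an explicit argument — published
profiles often leave it implicit, and defaulting it silently would change
every fold. Replicate SD is carried for plotting only; no cross-biological
statistics are computed because none are defined for single-colony
technical replicates. Enrichment in a target tissue requires the fold there
to be at least `min_fold = 2` times the fold in *every* other sample, ties
failing.

## The synthetic validation: what it shows and what it cannot

`generate_dataset()` builds the standard validation conditions: a reference
family of 10 proteins of 420 aa sharing six conserved 12-aa blocks at 35 %
elsewhere-divergence (mimicking a usable homology panel for a divergent
family); 18 implanted loci — 8 intact multi-exon genes (2–3 introns of
60–1,200 nt, both strands), 2 frameshifts, 1 premature stop, 1 five-prime
and 1 three-prime edge truncation (120 nt clipped at a scaffold edge), 1
N-gapped internal exon, an allelic pair (2 % nt substitutions plus one
codon-length gap, copy on an 8-kb contig) and a 2-gene tandem array (3 % nt
divergence) — in ~0.6 Mb of scaffolds including two gene-free decoys.
Implanted genes carry 2 % amino-acid substitutions relative to their source
reference, applied to internal residues and never creating a stop (a
functional gene has no internal stops; the start codon anchors the ORF):
this matches the divergence regime the curation rules are specified to
resolve exactly. Intron positions are drawn with ≥ 60 aa between splice
sites; copies never mutate splice dinucleotides or terminal codons, since
they model alleles/paralogs of functional genes.

These conditions validate the *machinery*: exact exon/intron recovery,
lesion flagging, allele/paralog resolution, naming, and all coordinate
conventions, end to end and deterministically. They do not reproduce real
receptor annotation difficulty: real queries sit at 40–60 % identity (not
98 %), real assemblies have sequencing error, repeats, and non-canonical
splice sites, and real intron length distributions are heavier-tailed.
Passing the synthetic suite therefore demonstrates correctness of the
implementation under its stated assumptions, not expected recall on a real
genome; on real data the search and chaining thresholds (`score_min`,
`min_hit_identity`, `min_chain_score`) are the knobs to relax first.

Problem sizes throughout (0.6-Mb genomes, 10-protein panels, 100–200
bootstrap replicates in examples, 1,000 as the standalone default) are
chosen so a full validation run completes in well under a minute on one
CPU, which keeps the whole suite runnable on every change.

## Known limitations

- Single-hit exons shorter than the two-hit trigger can be missed on long
  queries; the chain then bridges them as a (wrongly) long intron or a
  partial model.
- Splice refinement searches canonical GT–AG only.
- Locus deduplication keeps the top-scoring chain per genomic interval;
  genuinely overlapping genes (nested, antisense) would be collapsed.
- The allele rule compares CDS only; allelic copies diverged beyond 5 % nt,
  or split across contig boundaries, are retained as genes.
- No E-value model; score thresholds are raw and genome-size dependent.
- No PSI-iteration of the search with newly found family members as
  queries, and no selective-pressure (dN/dS) analysis: both are outside
  this package's scope.
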