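---
title: "Mining putative Ni-CO dehydrogenase genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining putative Ni-CO dehydrogenase genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcodh)
```

## The problem

Anaerobic carbon monoxide utilization by prokaryotes runs through
nickel-containing CO dehydrogenase (Ni-CODH), whose catalytic subunit
(CooS/CdhA) falls into phylogenetic clades A–H plus a mini-CODH form. Given a
collection of annotated prokaryotic genomes, `gutcodh` answers five
questions:

1. Which genes are *putative* Ni-CODH (pCODH) — homologous to
   clade-representative CooS sequences **and** conserving the active-site
   machinery (two C-clusters, a B-cluster, a D-cluster, two acid–base
   catalysts)? Which clade does each belong to? Are there any
   molybdenum-CODH (CoxL-like, AYRCSFR motif) genes?
2. What sits around each pCODH gene — which of eight marker-defined genomic
   context types (WLP, PEPCK, FNOR, ABC transporter, Fe-only hydrogenase,
   MFS transporter, uncharacterized dehydrogenase, cysteine synthase) does
   the ±15-gene neighborhood support?
3. Which genomes encode both pCODH and acetyl-CoA synthase (acsB, K14138) —
   the operational definition of a potential Wood–Ljungdahl-pathway (WLP) CO
   utilizer — and is their WLP gene set complete, or degenerated to the
   *Fdh-lacking* form (no formate-dehydrogenase catalytic subunit), with
   formate acquired instead through pyruvate formate-lyase (PFL),
   transporters, or neither?
4. Are the pCODH genes transcribed — detection, RPKM and TPM from
   metatranscriptome reads, aggregated by taxon and context type?
5. What are the headline counts and percentages?

Every stage is exercisable on synthetic genomes and reads with planted
ground truth; no external download or external alignment binary is needed.

## The screen

Candidates are found by Smith–Waterman local alignment (BLOSUM62, affine
gaps 11/1, via `Biostrings::pairwiseAlignment`) of every gene protein
against six clade-representative templates. A hit passes when all three
cutoffs hold:

* E-value ≤ 1e-10,
* alignment identity ≥ 30 % (matches / alignment columns),
* alignment length ≥ 200 columns.

Because the search runs in-process rather than through an external search
tool, the E-value needs an explicit model: Karlin–Altschul,
$E = K\,m\,n\,e^{-\lambda S}$, with gapped BLOSUM62 parameters
$\lambda = 0.267$, $K = 0.041$, query length $m$ and a configurable
effective database size $n$ (default $10^7$ residues — the scale of a few
thousand bacterial proteomes). The same statistics feed the reported bit
scores. Two readings of the "200 aa" length cutoff exist (alignment columns
vs. query coverage); the package uses alignment columns, the common reading
of tabular-output filters, and exposes the threshold as a parameter.
Precomputed 12-column tabular hits can be ingested instead of running the
in-process search; both paths apply identical pass/fail rules.

A gene is a candidate when at least one reference passes (the paper-style
workflow is silent on this; the inclusive rule maximizes sensitivity ahead
of the stricter motif filter). The clade call is the clade of the
highest-identity reference, ties broken by bit score then lexicographic
label. Clades are reported for motif-filter survivors; the filter-then-report
order is one of two defensible orders and is applied consistently.

## Motif validation

A candidate is confirmed as pCODH only if **no substitutions and no
deletions** occur at any configured active-site position. Positions live in
an editable config anchored to a named reference sequence, because exact
residue coordinates are inherited from the structural literature rather
than being universal constants; the shipped default is anchored to the
synthetic clade-F template and is a stand-in that must be re-anchored to a
curated CooS (e.g. a *C. hydrogenoformans* CooSII-style reference) before
use on real data.

Anchor positions are transferred to each candidate by global
Needleman–Wunsch alignment under the search's matrix and gap costs. Each
configured position then maps to a candidate residue (checked against the
allowed set) or to a gap (site `deleted`). If alignment identity falls below
20 %, all sites are reported `unaligned` — a distinct failing state, so
garbage mappings are never misreported as substitutions.

One mapping subtlety matters in practice: for candidates from a clade other
than the anchor's, candidate–anchor identity can sit near 25–30 %, where a
direct pairwise alignment occasionally misplaces an *isolated*
single-residue site by a column or two even though multi-residue cluster
sites stay put. The screening pipeline therefore composes the mapping
through the candidate's best-matching clade representative — two
high-identity pairwise alignments (anchor → representative → candidate) —
which is the pairwise analogue of the positional homology that a multiple
sequence alignment would provide. Direct mapping remains available and is
the default for the low-level functions.

The same machinery validates pyruvate formate-lyase: K00656 includes
PFL-like proteins without PFL activity, so a K00656 gene counts as PFL only
if both catalytic cysteines (adjacent Cys-Cys) are conserved against the PFL
anchor.

## Context typing

The window around a focal gene is **rank-based**: the genes whose ordinal
position along the contig lies within ±15 of the focal gene, regardless of
strand or intergenic distance, truncated at contig edges. Marker rules per
type are KO/COG sets; a type has evidence when its combination rule is
satisfied by non-focal window members (the focal gene's own annotations are
ignored — they may be misleading). The ABC-transporter type requires all
three subunit markers (K02049/COG0715, K02050/COG0600, K02051/COG1116)
across the window, configurable to two.

Windows can satisfy several types at once; assignment uses a fixed
precedence order — WLP > PEPCK > FNOR > ABC transporter > Fe-hydrogenase >
MFS transporter > uncharacterized dehydrogenase > cysteine synthase — which
codifies the reported dominance of WLP in co-occurring windows and otherwise
follows the types' reporting order. This precedence is this package's
explicit, documented substitute for what was a manual call in the original
workflow; secondary evidence is always preserved in the output, never
discarded. Auxiliary genes (oxyR, narGHIJK, pflAB, hypAB, cooC, cooF) are
tallied without affecting assignment. The narGHIJK KO list is a curated
default (the operon has no single canonical KO in the source material).

## WLP profiling

Presence is genome-wide, not window-restricted: a symbol is present when any
gene of the genome carries any of its KOs, with multi-KO genes counting for
every matched symbol. A genome is *pCODH/ACS-encoding* iff it carries a
motif-validated pCODH gene and acsB. `fdh_lacking` means none of the
catalytic Fdh subunits (fdhA K05299, fdhF K22015, fdoG K00123) is present;
the formate route is the first available of Fdh, Cys-Cys-validated PFL,
formate transporter (focA/focB/oxlT/yfdC/fdhC), or none. Genes co-annotated
with an Fdh KO and glutamate synthase (K00266) still count toward Fdh — the
co-annotation count is reported separately rather than silently excluded.
oxlT (K08177) intentionally appears both as an MFS context marker and as a
formate transporter; K00123 is kept under fdoG only so that no KO maps to
two symbols.

## Transcript quantification

A desk-scale pseudo-mapper replaces an external aligner: exact 31-mers of
each read vote for the genes containing them (the index covers both
strands), the top gene wins if it collects ≥ 50 % of the read's k-mers, and
ties are discarded as ambiguous. On error-free reads this is equivalent to
exact substring matching, which the tests verify against a brute-force
oracle. External per-gene count tables can be supplied instead, keeping
parity with mapper-based workflows.

RPKM uses `count / ((length/1000) × (mapped/1e6))` with **mapped = reads
assigned to the provided reference set**, not total sequenced reads — the
denominator choice is stated here prominently because mapper defaults vary.
TPM renormalizes RPKM to sum to $10^6$. Detection is ≥ 1 assigned read per
dataset — an explicit substitute for a criterion that upstream tooling never
printed. Covered positions (depth ≥ 1) are reported per gene so cover-length
filters (e.g. > 1500 nt) can be applied downstream, not built in.

## The synthetic-data generator

The generator is first-class, tested code; it emulates the statistical
structure the pipeline must recover, not the full biology:

* **Reference set** — six templates (clades B, C, D, E, F, mini), 630 aa.
  The clade-F template is the motif anchor; the others are derived from it
  at ~55 % identity with motif positions protected. This keeps all pairwise
  template identities below 60 % (mutual divergence ≥ 40 %) while
  guaranteeing that a candidate planted at ≥ 50 % identity to *any* template
  still maps reliably onto the anchor — with independent random templates, a
  cross-clade candidate would fall below the 20 % unaligned floor by
  construction, which would test nothing.
* **Planted genes** — `mutate_to_identity` performs substitution-only
  mutagenesis of exactly `round((1-t)·L)` positions, spread evenly along the
  sequence (one draw per contiguous block). Even spreading matters: it keeps
  local-alignment identity tracking global identity, so genes planted at
  28 % and 32 % fall on the correct sides of the 30 % cutoff instead of
  being inflated by trimming of mutation-dense ends. Motif damage is either
  one substitution in the first C-cluster or a deletion spanning the whole
  B-cluster; a single deleted residue adjacent to a conserved block is
  deliberately not planted, because no pairwise (or multiple) alignment can
  localize it — the gap floats among co-optimal columns and a neighboring
  residue can stand in.
* **Genomes** — background genes are random-codon ORFs of 200–700 aa with no
  annotations, so marker matches are unambiguous; intergenic spacing is a
  fixed 50 nt (windows are rank-based, so distances are irrelevant); context
  markers are placed at fixed small offsets from the focal gene; WLP
  gene-complement presets (full, Fdh-lacking with PFL / transporter /
  neither, none) go on a second contig.
* **Reads** — error-free, uniform position, reverse-complemented with
  probability 0.5, constant quality; drawn with probability ∝ weight ×
  gene length. Read QC is out of scope.

What passing tests therefore show: the screen, filter, typing, profiling and
quantification logic recover planted truth exactly under controlled identity
levels, motif states, marker placements and abundances. What they do not
show: behavior under annotation noise beyond planted decoys, sequencing
error, fragmented assemblies, real phylogenetic structure, or motif
coordinates of real CooS — the stand-in config must be reviewed before any
real-data use.

## Numerical and procedural choices

* Internal coordinates are 0-based half-open; on-disk GFF3 is 1-based
  inclusive. KO/COG annotations live in a TSV side table keyed by gene id;
  multiple KOs per gene are all retained.
* Gap cost of a length-L gap is `11 + L` (open 11, extend 1), matching the
  aligner's convention; the test oracle uses the same convention.
* Percentages are rounded half-up at the stated decimals (printed ratios
  such as 526/667 → 79 % match half-up, not banker's, rounding).
* Clade ties: higher bit score, then lexicographic clade label. Ambiguous
  reads: discarded, never fractionally assigned. Zero mapped reads: all-zero
  RPKM/TPM vectors. Empty genus labels group as `unassigned`.
* Determinism: every stochastic function takes a seed and uses it through a
  scoped RNG, so equal seeds give byte-identical outputs.

## Problem sizes in the shipped runs

The test suite screens a 60-genome cohort (10 per clade, identities
50–90 %, half intact / half damaged motifs), types 80 planted context
windows, profiles 100 genomes across the five WLP presets, and quantifies
10 000 reads against a brute-force oracle. The acceptance script
(`scripts/acceptance.R`) re-runs the same recoveries at 24 / 16 / 20 genomes
and 4 000 reads, sizes chosen so a complete from-scratch rerun stays
comfortably within a coffee break on one CPU while every recovery rate is
still measured over enough planted items to be meaningful.

## Known limitations

* The default motif coordinates are synthetic stand-ins (see above).
* Single-anchor pairwise mapping without a via-reference can misplace
  isolated sites below ~30 % identity; the pipeline path mitigates this but
  candidates with no high-identity reference remain hard — exactly the cases
  a curated MSA-based config should handle.
* The pseudo-mapper assumes error-free reads; with sequencing errors its
  exact-k-mer votes lose reads long before a real aligner would.
* No operon prediction, no tree building, no figure rendering, no
  co-occurrence significance testing: out of scope by design.
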