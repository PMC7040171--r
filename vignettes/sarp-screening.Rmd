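---
title: "SARP-guided screening of biosynthetic gene clusters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SARP-guided screening of biosynthetic gene clusters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarpscout)
```

## The biological problem

Actinomycete genomes typically encode 20-30 biosynthetic gene clusters
(BGCs), most of which are silent under laboratory conditions. Streptomyces
Antibiotic Regulatory Proteins (SARPs) are pathway-specific transcriptional
activators of such clusters: an N-terminal winged helix-turn-helix (HTH)
domain binds a conserved DNA recognition sequence, and a C-terminal
bacterial transcriptional activation domain (BTAD) recruits RNA polymerase.
The recognition sequence is a degenerate heptamer, `GTCAGSS` in IUPAC
notation (S = G or C) for PapR2-like SARPs, occurring as direct repeats
separated by 4 bp spacers, usually overlapping the -35 region of the target
promoter.

Because one well-characterized SARP can substitute for a related native
activator, clusters that (i) encode a SARP highly similar to the
characterized reference and (ii) carry the reference's binding motif in a
promoter region are strong candidates for activation simply by expressing
the reference SARP in the strain. `sarpscout` turns that screening logic
into a reproducible desk pipeline: motif scanning, intergenic filtering,
SARP architecture classification, reference-similarity scoring, and gated
prioritization.

## Coordinate and sequence conventions

All interval arithmetic is 0-based half-open internally; user-facing
exports use each format's native convention (BED stays 0-based, GenBank
output and the localization strings are 1-based inclusive). Sequences are
upper-cased on read; ambiguity codes other than N are rejected unless the
reader is asked to normalize them to N. N never matches any motif
position, so masked stretches cannot create hits. Compound (join) CDS
locations are flattened to their span with a warning -- spliced bacterial
CDS are rare and the flattened span is conservative for intergenic
filtering (it can only shrink intergenic space, never invent it).

"Intergenic" means not covered by any CDS on either strand, including the
stretches before the first and after the last CDS of a replicon. A record
without CDS is one single intergenic region, not an error.

## Motif model and scoring

The motif model is the IUPAC consensus plus repeat geometry
(`repeat_count` heptamer units, `spacer_length` bases between them).
Scoring is identity to the consensus: a site base matching the allowed set
at its position scores 1, so a G or C at an S position is a *full* match
-- the reading forced by sites being reported as "100%" identical to a
degenerate consensus. Spacer positions are unscored by default. The
`tri_heptamer` preset scores them as always-matching positions in both
numerator and denominator, giving 29 scored positions for a three-unit
site: a single heptamer mismatch is then 28/29 = 96.6% and a badly eroded
site can sit at 19/29 = 65.5%, matching how conserved and weak sites are
quoted in the field. The default genome-scanning model stays the single
heptamer with `min_identity = 6/7` (at most one mismatch); the exact
mismatch allowance used by historical PatScan screens is not documented,
so it is a configurable parameter rather than a constant.

Scanning slides every window of the site span over both strands;
minus-strand hits are reported in plus-strand coordinates with the site
sequence given 5'->3' on the hit strand. Hits are sorted by start, `+`
before `-` at ties; overlapping hits are all kept (no greedy masking),
because downstream filters -- not the scanner -- decide biological
relevance. Tandem sites are found either directly (a multi-unit model) or
by chaining single-heptamer hits at the heptamer+spacer period with
`find_repeat_arrays()`.

## Promoter windows

Experimentally validated SARP binding has been shown in 182-230 bp
upstream fragments. The default promoter window is 350 bases upstream of
the translational start, clipped at the nearest upstream CDS boundary:
wide enough to cover the experimentally validated range with margin,
narrow enough to bound the search space. How far upstream a genome-wide
hit may sit and still be called a "promoter" motif is not something the
source screening data pins down, which is why the window length is an
explicit parameter everywhere it is used.

## SARP identification and census

Family membership is read from profile hits against four PFAM domains:
PF00486 (Trans_reg_C, the HTH), PF03704 (BTAD), PF00931 (NB-ARC) and
PF13424 (TPR_12). PF93704 -- a nonexistent accession that circulates as a
typo for PF03704 -- is accepted as a BTAD alias. Architecture is a total
function of the roles present: HTH+BTAD alone is a *small* SARP, HTH+BTAD
plus NB-ARC and/or TPR is *large*, BTAD without HTH and HTH without BTAD
are kept as separate degenerate classes, and anything else is
*incomplete*. Degenerate classes matter: BTAD-only proteins are a
recognized subfamily signal in Micromonosporales, while family-profile
hits with neither HTH nor BTAD (common in Proteobacteria) are likely not
SARPs at all -- which is why genome-level "SARP-positive" requires at
least one protein in a non-incomplete class.

All percentages -- census shares, prevalence, cluster similarity -- use
round-half-up to the nearest integer. This single rounding rule
recomputes every published census worked example exactly from its counts
(611/625 -> 98, 115/276 -> 42, 79/1236 -> 6, 38/39 -> 97, 3289/6525 -> 50,
1080/6525 -> 17, 330/1080 -> 31, 184/822 -> 22), which is the check the
acceptance suite runs.

## Reference similarity

`pairwise_similarity()` is a global (end-gap-penalized) Needleman-Wunsch
alignment with BLOSUM62, gap open 10, gap extension 0.5. Identity is the
fraction of identical columns over *all* alignment columns; similarity
additionally counts columns with a positive substitution score; gap
columns inflate only the denominator, so identity <= similarity <= 100 by
construction. Because co-optimal global alignments can differ with
argument order, the pair is canonically ordered before aligning, making
the reported percentages exactly symmetric. Global alignment is a
deliberate departure from BLASTP (local): it is deterministic,
parameter-light, and appropriate for comparing full-length regulators of
similar length. Consequently no claim is made of reproducing
BLASTP-derived percentages for any specific protein pair; the >55%
similarity gate is applied to this global similarity.

## Cluster similarity and annotation

The gene-similarity rule is strict on all three axes: e-value < 1e-5,
identity > 30%, and alignment coverage > 25% of the *shorter* sequence.
Cluster similarity to a known reference cluster is the rounded percentage
of reference genes with at least one passing counterpart; one query gene
may support several reference genes. The rule consumes precomputed hit
tables from any aligner rather than re-running BLAST.

Per-cluster annotation counts SARP genes whose span lies inside the
region (partial overlaps are counted but flagged separately, since the
screening convention for boundary-straddling genes is not defined
anywhere authoritative), attaches the best reference similarity among
them, and attaches motif hits that fall inside the region *and* inside an
intergenic interval -- a motif inside coding sequence is discarded as
biologically implausible regardless of its score.

## Prioritization gates

Three gates, all configurable: (a) the cluster contains at least one SARP
gene, (b) the best cluster-situated SARP exceeds 55% similarity to the
reference (strict `>`, following the published phrasing; switchable to
`>=`), (c) at least one intergenic motif hit at or above the scan
threshold lies in the cluster. A cluster passing all enabled gates is a
candidate; a strain is prioritized if any cluster is. Whether the motif
must sit in the *same* cluster as the SARP gene is genuinely ambiguous in
the source strategy (screens have flagged clusters with a motif but no
SARP gene); both modes are supported via
`require_cluster_situated_sarp`, and when it is disabled both SARP gates
are skipped -- the interpretation being that a trans-acting SARP
elsewhere in the genome may drive the cluster.

The ranking (best motif identity, then best reference similarity, then
cluster id) is an invention of this package -- the strategy it implements
prioritizes but defines no total order -- and is documented as such.
Ordering and float formatting in the report writer are fixed so identical
inputs give byte-identical reports.

## The synthetic world

`simulate_genome()` emits the complete input set -- GenBank genome,
region BED, domain-hit TSV, protein FASTA, reference FASTA -- with a
truth table. Its defaults are a fixed, stated world: three clusters of
four 900 bp genes separated by 150 bp intergenic gaps at GC 0.72
(Streptomyces-like); a synthetic 280-residue reference SARP; planted SARP
similarities of 60% and 40% straddling the 55% gate; one perfect motif in
each of the first two clusters and none in the third, so exactly one
cluster passes all gates. Planted similarities are achieved by mutating
the chosen fraction of residues to BLOSUM62-nonpositive replacements, so
the gapless global alignment lands on the target by construction (the
optimizer occasionally introduces a gap or two, moving the realized value
by under 2 points -- far from either side of the gate). Planted motifs
mutate consensus positions to bases *outside* the IUPAC-allowed set, so a
k-mismatch site scores exactly (7-k)/7.

Two features of real data are deliberately absent. First, chance
near-consensus heptamers: a GC-rich background produces them at a rate
that would make "a cluster without a motif" unconstructable, so the
generator scrubs intergenic gaps of windows reaching the scan threshold
(default 6/7), leaving the planted sites as the only qualifying
intergenic motifs. Real genomes are *not* scrubbed -- in application, the
intergenic filter and the gates do that work statistically, not
deterministically. The false-positive-rate check therefore runs on plain
uniform (GC 0.5) unscrubbed background, where the analytic perfect-match
rate is 4/4^7 per strand-position. Second, realistic protein and codon
structure: SARP CDS are reverse-translated with one fixed GC-rich codon
per residue and all other genes are random DNA, so a green end-to-end
test establishes pipeline correctness, not detector performance on real
genomes.

All randomness in the generator flows from one integer seed through R's
default RNG; the same seed gives byte-identical files.

## Numerical choices and degenerate inputs

Identity thresholds are compared with a 1e-12 tolerance so 6/7 computed
two ways cannot straddle the gate. Empty sequences scan to empty hit
tables; a zero-CDS record is one intergenic region; an empty region table
annotates to an empty report; `classify_architecture` is total, including
the empty hit set. Validation failures (coordinates outside the replicon,
unknown gene ids, cross-record id mismatches, empty reference gene sets)
raise errors naming the offender rather than returning silently empty
results.

## Known limitations

Position-weight-matrix scoring, motif discovery, and hit p-values are out
of scope, as are BGC boundary prediction and running the profile-HMM
search itself (hit tables are consumed, not produced). The GenBank parser
covers the flat-file subset that annotated bacterial genomes and
antiSMASH region files use, not the full standard. Phylogenetic grouping
of SARPs -- the natural next step for choosing activator bricks -- is not
attempted.
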