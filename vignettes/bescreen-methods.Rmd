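---
title: "Models and methods behind bescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescreen)
library(dplyr)
```

`bescreen` supports the full computational arc of a cytidine-base-editor
(BE3-class) substitution-mutation screen: designing an sgRNA library against
annotated coding sequence, scoring guide specificity, quantifying editing
outcomes from amplicon deep sequencing, counting guides in pooled-screen
reads, and assigning guides to single cells with multiplicity-of-infection
(MOI) inference. This vignette explains the models, conventions and numerical
choices; the README shows the quick workflow.

## Coordinates and gene models

All internal coordinates are 0-based half-open; GTF input/output is 1-based
inclusive, so internal start = GTF start − 1 and internal end = GTF end. A
`gene_model` keeps each isoform separate (no "canonical isoform" collapsing),
stores CDS intervals in coding order, splices and reverse-complements
minus-strand CDS, and trims the first interval's frame before codon
numbering. Isoforms whose spliced CDS length is not divisible by 3 are
flagged, kept in the table, and simply contribute no trailing codon; they are
excluded from design by the absence of complete codons rather than dropped
silently. Stop codons receive no special handling: the CDS is used exactly as
annotated.

`codon_at()` is the pivot every classification rests on: given a genomic
position it returns the containing codon, its 1-based residue index and the
genomic positions of all three codon bases, correctly assembling codons split
across exon junctions.

## Guide design and outcome enumeration

A BE3-class editor converts C to T within an activity window of the
protospacer. Conventions used throughout:

* protospacer positions are numbered 1–20 with 1 at the **PAM-distal** end;
* the activity window is positions 4–8 (inclusive), configurable;
* PAM classes are NGG (canonical) and NAG (tolerated, lower activity; off by
  default and enabled by a flag).

`scan_candidates()` emits every 20-mer followed by an allowed PAM on both
strands before any filtering. `filter_editable()` keeps candidates with at
least one window C whose genomic position lies in the CDS of at least one
isoform, recording editable sites per isoform.

`enumerate_outcomes()` enumerates **all non-empty subsets** of a candidate's
editable window Cs. Subset enumeration is the only reading under which one
guide can produce several mutation types (silent, missense, nonsense alone or
in combination), which is what a screen designer needs to anticipate. Edits
within one outcome are same-strand only: a deamination event converts Cs on
one strand, so an outcome is either C→T on the coding strand or G→A on the
coding strand (the image of editing the opposite strand), never a mixture.
Outcomes spanning two codons report both changes (notation joined by `/`) and
take the most severe class, with severity ordered nonsense > missense >
silent. Cs outside the window are **not** edited during enumeration, but each
candidate carries all protospacer C positions and a TC-motif flag, because
APOBEC1 prefers TC and can edit efficiently outside the window (a known
failure mode when a TC lies at, say, positions 13–15); users can screen
candidates for that risk without changing design semantics.

The amino-acid conversion matrix (`aa_conversion_matrix()`) is a pure
codon-table computation under the same edit model: 13 of the 20 canonical
amino acids can be converted to a different amino acid, and the remaining 7
(F, I, K, N, Q, W, Y) admit only silent or nonsense changes. Mixing C→T and
G→A within one codon would inflate the first count to 17, which is why the
same-strand restriction matters.

Coverage statistics define a residue as *targetable* when at least one
outcome changes its amino acid (missense or nonsense); silent-only residues
are reported separately and can be included with `include_silent = TRUE`,
since reasonable users may want either convention. A locus counts as "covered
by more than one sgRNA" when two or more distinct candidates have an outcome
at it; the denominator is the set of covered loci. Clinical-variant coverage
asks for exact producibility of (gene, residue, ref, alt) rows; rows naming
unknown genes are skipped and counted.

`group_by_target_overlap()` partitions candidates by the transitive closure
of "same target strand and protospacer intervals overlap ≥ 1 base" — the
grouping used when asking whether guides at the same locus behave
concordantly downstream.

## Off-target specificity

The specificity score of a guide is

$$
S \;=\; \frac{1}{1 + \sum_{i=1}^{n} \mathrm{CFD}_i},
$$

over off-target sites with at most 3 mismatches in the 20-mer (the PAM is
scored by a class factor, not counted as mismatch), restricted to coding
sequence and to sites a base editor could act on: off-target protospacers
without a window C are excluded, as are PAM classes other than NGG/NAG. A
unique guide scores exactly 1 and every added hit strictly lowers the score.
Each site's CFD term is the product of per-(position, spacer base, off-target
base) mismatch factors times the PAM factor.

The packaged penalty table is **synthetic** — a smooth stand-in with the
qualitative structure of published mismatch-activity data (penalties shrink
toward the PAM-proximal end, transversions penalised slightly more than
transitions, NAG at 0.25) — and is clearly labelled as such in the file name.
Correctness of the scoring machinery never depends on the table's numeric
content (all tests use explicit synthetic tables), and calibrated tables can
be supplied via `read_cfd_table()`. Search is a direct
`Biostrings::vmatchPattern` scan over user-supplied coding sequence, which is
the right tool at desk scale; genome-scale indexed search and bulge scoring
are out of scope. One perfect-match site is excluded as the guide's own locus
(it contributes the 1 in the denominator); with duplicated loci the remaining
perfect copies count as off-targets.

## Amplicon quantification

Read processing follows a strict, literal pipeline:

1. **QC**: reads with more than 50% of bases below Q30 are discarded —
   exactly half is kept (strict ">") — and every base below Q30 in surviving
   reads is masked to N.
2. **Protospacer extraction**: the 10-nt flanks on both sides of the
   protospacer+PAM identify the segment; matching is exact by default (an
   option allows 1 mismatch per flank), first occurrence wins, a 3' flank
   preceding the 5' flank leaves the read unmatched, and orientation is
   auto-detected by retrying the reverse complement.
3. **Indel classification**: a segment is an indel read exactly when its
   length differs from 23 nt. No other heuristic.
4. **Base counts** are taken over indel-free segments; an N removes a read
   from that position's denominator only, not from the whole table.

Substitution efficiency at a position is

$$
\mathrm{eff}(p) = \frac{\text{reads with C→T at } p}{\text{indel-free reads covering } p}
\times (1 - \text{indel fraction}),
$$

where the denominator is indel-free flank-matched reads (consistent with
taking base frequencies across reads without indels) and the
$(1-\text{indel fraction})$ factor rescales to all flank-matched reads. Only
target-strand C→T counts toward efficiency; other substitutions are tabulated
but not folded in. When the protein-coding strand is the non-target strand,
tables are reported on the coding strand, where the conversion reads G→A at
the mirrored position. Codon-level allele tables translate each segment at
mapped codons (N-containing codons excluded from that residue's denominator),
and haplotype tables count the joint base pattern across the window Cs — the
readout for processive deamination, which converts multiple cytosines on the
same strand in one event and so produces all-or-none patterns.

Merged single-end reads are assumed; paired-end merging, alignment-based
indel characterisation and quality recalibration are upstream and out of
scope.

## Pooled-screen counting and enrichment

A read increments a guide exactly when it contains the guide's 20-nt spacer
as a substring, forward orientation by default (the vector fixes read
orientation; a `revcomp` flag enables both). Reads matching two different
spacers are ambiguous and excluded; unassigned reads are tallied.
Normalisation is reads-per-scale plus pseudocount
(`raw / total × 10⁶ + 1` by default) — the convention of earlier pooled-screen
work, exposed as parameters since the exact formula is a community
convention rather than something this toolkit derives. Log2 fold-change is
the log-ratio of normalized treatment to control counts; a guide absent from
one sample enters as raw 0, so the pseudocount keeps all values finite.
Guide-level negative-binomial p-values are deliberately not reimplemented:
the count table is written in a layout MAGeCK-class tools accept.

## Single-cell guide assignment and MOI inference

Per cell, distinct UMIs are counted per guide after collapsing duplicate
(cell, UMI, guide) triples, and the most abundant guide is assigned. Ties
leave the cell ambiguous and unassigned by default (a lexicographic
tie-break exists for reproducibility studies).

MOI and detection rate are fitted jointly by maximum likelihood under the
simplest model consistent with the two quantities: true integrations per
cell $K \sim \mathrm{Poisson}(\lambda)$ conditioned on $K \ge 1$ (antibiotic
selection removes uninfected cells — hence zero truncation), and detected
guides $D \mid K \sim \mathrm{Binomial}(K, d)$. Cells in the universe with no
detected guide contribute $P(D=0)$, which is what makes $(\lambda, d)$
identifiable. The likelihood is maximised on a coarse grid
($\lambda \in [0.01, 10]$ log-spaced, $d \in [0.01, 1]$, 25 × 25 points)
followed by Nelder–Mead refinement on $(\log\lambda, \mathrm{logit}\, d)$;
the fit is deterministic. The Poisson tail is truncated adaptively
($k_{\max} \ge \lambda + 12\sqrt{\lambda}$), at which point the pmf sums to 1
to numerical precision. Multiple integrations of the same guide are treated
as distinct detectable events — an approximation that is accurate for
hundreds-of-guides libraries where same-guide collisions are rare.

## Simulators and what they do (and do not) show

Every generator returns a machine-readable truth object and is byte-identical
under a fixed seed, so each estimator is tested as truth recovery.

* `sim_mini_genome()` builds one contig per gene from random sense codons
  (no internal stops, ATG start), mixes strands, optionally splits a codon
  across a two-exon junction, and plants an E→K cassette: a GAG codon whose
  first-base G is reached through an opposite-strand window C at protospacer
  position 6 (with the wobble G at position 4), under an NGG-class PAM. The
  planted default residue is 203, matching the geometry of a
  vemurafenib-resistance codon; editing position 6 alone gives E→K, position
  4 alone is silent, and both together still give lysine (GAG→AAA), the
  two-substitution variant pattern a deaminase plausibly produces.
* `sim_amplicon_reads()` edits window Cs with per-position rates under a
  processivity coefficient $p$: with probability $p$ one uniform draw drives
  all positions (comonotone coupling — marginal rates are preserved for any
  $p$, and with equal rates the patterns are all-or-none), otherwise
  positions are independent. Indels follow configurable alleles, defaulting
  to an 18-nt in-frame insertion and a 3-nt deletion — the two indel classes
  a nickase-based editor realistically leaves. Qualities are Q37 with a
  configurable fraction of Q14 bases to exercise the masking path.
* `sim_screen()` evolves guide frequencies multiplicatively
  ($\propto p_0 e^{st}$) under treatment and neutrally under control, with
  multinomial read sampling at fixed depth.
* `sim_cell_guides()` draws zero-truncated Poisson integrations, uniform
  guides, Bernoulli detection and Poisson-shifted UMI counts.

The simulators emulate the statistical structure these analyses assume; they
do **not** model sequencing substitution errors beyond quality masking, PCR
jackpotting, guide-specific editing efficiency, chromatin context, or
transcriptome readouts. Passing recovery tests therefore demonstrates that
the estimators are correct for their models, not that the models capture
every feature of real screen data.

## Problem sizes and numerical notes

The test-suite and reproduction script use desk-scale problems chosen to make
sampling error small relative to the tolerances asserted: 10,000 reads for
amplicon recovery (binomial SE ≤ 0.5 percentage points at the rates used),
10,000 cells per MOI fit (SE ≈ 0.03 on λ at the first operating point),
100,000 reads per screen sample with 420 guides, 10-kb off-target search
spaces with 100 spacers, and 50 random mini-genes for the design oracle.
Recovery checks on jointly asserted positions use simultaneous
(Bonferroni-corrected) binomial bands at the 95% level.

Degenerate inputs are handled explicitly: sequences shorter than 23 nt scan
to an empty candidate set; zero-coverage positions report `NA` efficiency; an
all-zero detection histogram is rejected as unidentifiable; empty guide
libraries are an error for counting; zero totals are an error for
normalisation. Ties in guide assignment are ambiguous rather than broken
arbitrarily.

## Known limitations

* Off-target search is desk-scale (direct scan, no genome index; no bulges).
* The packaged CFD table is synthetic; absolute specificity values are only
  as good as the penalty table supplied.
* Editing-efficiency prediction (position- and context-dependent activity)
  is out of scope; the design module enumerates what is *introducible*, not
  how *likely* each edit is.
* The MOI model ignores same-guide multiple integrations and assumes a
  homogeneous detection rate across cells.
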