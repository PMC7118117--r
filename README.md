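# bescreen

Design and analysis toolkit for **base-editor substitution-mutation
screens** — pooled CRISPR screens in which a Cas9-nickase–cytidine-deaminase
fusion (BE3-class) introduces C→T point mutations instead of knockouts, and
the mutation a cell carries is tracked through its integrated sgRNA, in bulk
(amplicon and screen sequencing) or per cell (CROP-seq-style capture).

It is aimed at groups building or analysing such screens: people who need to
ask *which amino-acid changes can a deaminase reach in my genes, with which
guides, how specifically* — and then, after the experiment, *what did the
editor actually do, which guides were selected, and which guide does each
cell carry*.

## What it computes

**Design.** Every 20-mer protospacer followed by an NGG (optionally NAG) PAM
on either strand of annotated CDS, filtered to guides with a cytosine in the
activity window (protospacer positions 4–8, PAM-distal numbering) lying in
coding sequence. For each guide, **all** introducible mutations: every
non-empty subset of window Cs is edited on the target strand (C→T, appearing
as G→A on an opposite coding strand), codons are rebuilt through the
exon-aware gene model, and each outcome is classified silent / missense /
nonsense with `E203K`-style notation. Library-level coverage: fraction of
residues targetable, loci covered by >1 guide, mutation-type spectrum,
clinical-variant coverage. The reachable amino-acid conversion matrix of the
editor is a pure codon-table fact the package computes: 13 of 20 amino acids
can be converted to another amino acid; 7 only to silent or nonsense
outcomes.

**Specificity.** Off-target sites with ≤3 mismatches in coding sequence,
filtered to editable sites (window C present, NGG/NAG PAM), scored with the
multiplicative CFD mismatch-penalty model, and aggregated as

```
specificity = 1 / (1 + Σ CFD over off-target sites)
```

so a unique guide scores exactly 1. The packaged penalty table is a clearly
labelled synthetic stand-in; supply calibrated values via `read_cfd_table()`.

**Amplicon quantification.** Q30 masking and the >50%-low-quality discard
rule, protospacer extraction by 10-nt flanks with orientation auto-detection,
indel classification by segment length ≠ 23, per-position base counts and
substitution efficiencies `C→T reads / covering reads × (1 − indel
fraction)`, codon-level amino-acid allele fractions, and window co-conversion
haplotypes (the processive-deamination readout).

**Screen counting.** Exact-substring spacer counting with ambiguity
exclusion, reads-per-million + pseudocount normalisation, per-guide log2
fold-changes, and representation summaries across timepoints.

**Single-cell guides.** Per-cell distinct-UMI guide counts, most-abundant
assignment with tie flagging, and maximum-likelihood estimation of MOI λ and
detection rate d under a zero-truncated Poisson + binomial-thinning model.

**Simulators** generate every input above with known ground truth
(mini-genomes with a planted E→K target, edited amplicon reads with tunable
processivity and indel alleles, selection screens, cell–guide capture
records), so the whole toolkit is testable offline.

## Worked example

```r
library(bescreen)
library(dplyr)

dir <- tempfile()
sim <- sim_mini_genome(seed = 7, dir = dir)   # FASTA + GTF + truth table
genome <- load_genome(file.path(dir, "genome.fa"))
models <- load_gene_models(file.path(dir, "annotation.gtf"), genome)

cand <- filter_editable(scan_candidates(genome), models)
outc <- enumerate_outcomes(cand, models)
export_library(cand, outc) |>
  select(guide_id, gene, spacer, strand, best_outcome, outcome_classes) |>
  head(4)
#> # A tibble: 4 × 6
#>   guide_id gene   spacer               strand best_outcome outcome_classes
#> 1 sg0004   gene01 TCACGGAGGAAGTTTCGGAT -      R9H          missense
#> 2 sg0005   gene01 ATCACGGAGGAAGTTTCGGA -      R9H          missense
#> 3 sg0006   gene01 CCGAAACTTCCTCCGTGATT +      N6N          silent
#> 4 sg0007   gene01 CCGAATCACGGAGGAAGTTT -      D10N         missense

coverage_stats(outc, models)
#> <coverage_report>
#>   3 isoform(s); mean targetable-residue fraction 0.203
#>   mean fraction of covered loci with >1 sgRNA 0.305
```

The mini-genome plants a GAG (Glu) codon at residue 203 reachable only
through an opposite-strand window C. The design pipeline recovers it:

```r
planted <- cand |> filter(spacer == sim$truth$spacer)
outc |> filter(guide_id == planted$guide_id) |> select(edit, class, notation)
#>   edit  class    notation
#> 1 4     silent   E203E
#> 2 6     missense E203K
#> 3 4+6   missense E203K
```

Editing window position 6 (the codon's first-base G, read as C on the guide
strand) gives the lysine substitution; position 4 alone is a wobble-position
silent change; both together still encode lysine (GAG→AAA). Specificity of
that guide against the mini-genome's coding sequence:

```r
cds <- setNames(vapply(models$model, \(m) m$cds, character(1)), models$tx_id)
specificity_score(planted$spacer,
                  filter_offtargets(find_offtargets(planted$spacer, cds)))
#> <specificity_result> GCTCTCAAACTTGCTACCAA: 0 hit(s), sum CFD 0.0000, score 1.0000
```

Single-cell MOI inference on simulated capture data:

```r
gs <- sim_cell_guides(0.83, 0.66, n_cells = 10000, n_guides = 420, seed = 1)
fit <- estimate_moi(detection_histogram(build_cell_guide_matrix(gs$records), gs$cells))
glance(fit)
#> # A tibble: 1 × 5
#>   lambda detection_rate  logLik converged n_cells
#> 1  0.811          0.662 -10766. TRUE        10000
```

Result objects have `tidy()` / `glance()` methods and `autoplot()` /
`plot_*()` ggplot views (per-position efficiency, representation boxplots,
observed-vs-fitted detection histograms, enrichment ranks). A thin CLI over
the same functions lives in `exec/bescreen`
(`design`, `specificity`, `quantify`, `count`, `enrich`, `sc-assign`,
`moi-fit`, `simulate`).

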