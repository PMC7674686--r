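# paralogon

Reconstruction of early gene-family evolution on a species tree annotated
with whole-genome duplications (WGDs), combining three lines of evidence
the way comparative genomicists do by hand: bootstrap-supported gene-tree
clades, conserved microsynteny, and the quadruplication structure left by
the two rounds of WGD (2R) at the base of the vertebrates.

The package ships a complete worked fixture: a survey of the tumor
necrosis factor superfamily (TNFSF) in ten vertebrates — three agnathans
(hagfish and two lampreys), two chondrichthyans (whale shark, elephant
shark), three actinopterygians (zebrafish, torafugu, spotted gar), the
coelacanth, and human — classified into 24 orthology groups organised in
five gene clusters (TNF, EDA, FASL, CD40L, 4-1BBL). From the printed
count matrix, the species tree and a table of origin constraints, the
package reconstructs where every orthology group was born, which lineages
lost it, and where tandem duplicates accumulated.

## Who this is for

Molecular evolutionists studying gene-family remodeling across deep
vertebrate phylogeny: anyone with (i) a species × orthology-group count
matrix, (ii) a rooted species tree with WGD events placed on branches,
and optionally (iii) gene trees with bootstrap supports and BED-like
gene-order tracks. Everything is data-frame in, tibble out, so results
compose with dplyr/ggplot2 workflows.

## The model

**Orthology grouping.** Leaves of a gene tree are grouped by supported
clades (bootstrap ≥ 95% by default). A supported clade containing
reference genes that no supported internal branch can separate
*species-consistently* defines one merged group (this is how the
inseparable human TNFSF1/LTα and TNFSF2/TNF genes become the single
TNFSF1/2 group). Leaves stranded outside supported clades can be rescued
by microsynteny: a shared immediately-adjacent orthologous neighbour
("same position") or a neighbour whose ortholog sits on the partner's
chromosome ("same chromosome").

**Chance-collision model.** A shared flanking gene is accepted as proof
of synteny because the probability of a chance collision is
`slots / N` — with four candidate flanking slots in a genome of
N = 20,000 genes, p = 1/5,000. Independent congruent comparisons
multiply: two same-position hits at 2×10⁻⁴ combine to 4×10⁻⁸.

**Event reconstruction.** Presence of each group evolves under Dollo
parsimony (a single origin, losses only thereafter); copy numbers evolve
under Wagner parsimony (integer states, cost |Δ| per branch, one copy
deposited at the origin). Both are solved in one Sankoff dynamic program
with the no-regain rule, ties broken towards the smallest ancestral
count. Origin constraints pin groups to WGD1/WGD2 (with a progenitor and
paralogon — ancestral chromosome 9 or 16 — label) or to a tandem
duplication of a named parent on a named branch; constrained origins may
force losses plain Dollo would avoid. Copy gains on the branch carrying
the teleost-specific WGD are labelled retentions of that event.

**Simulator.** A seeded birth–death generator produces event histories,
count matrices, gene-order tracks and support-annotated gene trees with
the statistical structure the analysis assumes (single-origin families,
WGD-correlated gains, lineage losses, tandem duplicates adjacent to
their parents, locally conserved neighbourhoods), so the whole pipeline
is testable end to end without any genome database.

## Worked example

```r
library(paralogon)

m    <- tnfsf_counts()       # 10 species x 24 groups (+ "Other")
st   <- tnfsf_tree()         # WGD1+WGD2 on the vertebrate stem, TS-WGD on the teleost stem
cons <- tnfsf_constraints()  # the five-cluster origin model as data

h <- infer_history(m, st, cons)
h
#> <event_history> 24 groups, 82 events across 17 branches

glance(h)
#>   n_groups n_origins n_losses n_copy_losses n_duplications n_wgd_retentions root_repertoire
#> 1       24        24       34             0             24                0              15

nrow(ancestral_repertoire(h, "vertebrate_ancestor"))
#> [1] 15
progenitor_count(h, cons)
#> [1] 3
post_wgd_gene_count(h, cons)
#> [1] 13

conservation_summary(m, st)
#> <conservation_summary> 24 groups across 10 species
#>  universal: TNFSF6, EDA
#>  shared (both sides, not universal): 7
#>  Homo_sapiens-side only: 15; absent in Homo_sapiens: 7
```

Reading: three pre-WGD progenitor genes were quadruplicated by the two
ancestral WGDs into 13 genes, two post-WGD tandem duplications (BALM and
TNFSF-Fish2) brought the vertebrate ancestor to 15, and the agnathan
lineage then lost six of them (`tidy(h)` lists the per-branch events;
the losses on `agnathan_ancestor` are TNFSF1/2, -10, -11, -12, -13 and
-15). Only TNFSF6/FASL and EDA survive in all ten species.
`autoplot(h)` draws the per-branch event counts, `autoplot(m)` the count
matrix; `run_pipeline()` wraps the stages into a self-describing run
directory with a machine-readable `summary.json`.

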