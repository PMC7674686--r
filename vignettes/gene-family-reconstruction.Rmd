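---
title: "WGD-constrained reconstruction of gene-family histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WGD-constrained reconstruction of gene-family histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## The problem

Ancient gene families leave a weak phylogenetic signal: single-domain
alignments rarely give statistical support to the deep branches that
relate paralogs born hundreds of millions of years ago. Comparative
genomicists therefore reconstruct early family evolution by triangulating
three other signals — well-supported *shallow* clades (orthology groups),
conserved gene neighbourhoods (microsynteny), and the quadruplication
pattern left by the two whole-genome duplications (2R, here WGD1 and
WGD2) at the base of the vertebrates. `paralogon` turns that manual
argument into a reproducible pipeline, and ships the tumor necrosis
factor superfamily (TNFSF) in ten vertebrates as its worked fixture.

The pipeline has four stages, each usable on its own:

1. **orthology grouping** (`classify()`) from a bootstrap-annotated gene
   tree plus optional synteny evidence;
2. **synteny evaluation** (`neighborhood()`, `shared_neighbor_evidence()`,
   `chance_probability()`, `corroborate()`);
3. **event reconstruction** (`place_origin()`, `infer_history()` and the
   summaries built on it);
4. **simulation** (`simulate_history()` and friends) providing ground
   truth for validation.

## Orthology grouping

A branch is treated as informative only when its bootstrap support
reaches `min_support` (default 95%, the conventional significance
threshold for ultrafast bootstrap values); missing supports count as 0.
Assignment rules, in order:

1. A supported clade containing reference genes that no supported
   internal branch separates *species-consistently* defines one group,
   named by its reference gene(s); two or more inseparable references
   merge into a slash-joined name (TNFSF1 + TNFSF2 → "TNFSF1/2"). We
   define a separating branch as one where each side holds at most one
   reference gene and every non-reference species' leaves fall entirely
   on one side: only then can per-species orthology be read off the
   topology. The *smallest* qualifying clade containing a leaf decides
   its group, so nested resolved structure is always preferred to an
   enclosing merge.
2. A supported clade with no reference gene spanning at least two
   species is a novel group. Maximal such clades are used and auto-named
   `GRP-` plus the lexicographically smallest member accession, for
   determinism.
3. A leaf outside every qualifying clade is rescued into a group it
   shares `same_position` or (failing that) `same_chromosome` synteny
   evidence with. Equal-class evidence towards two different groups is a
   conflict and the leaf stays `UNASSIGNED` — we never break such ties
   arbitrarily.

One behavioural subtlety is worth knowing: the number of groups is *not*
strictly monotone in `min_support` when supports are noisy. A family
clade can fall below the threshold while one of its internal paralog
clades stays above it, so a reference-anchored group can be replaced by
a novel sub-group. With noise-free supports the count is monotone
non-increasing, and under noise the replicate-averaged count still is;
the test suite checks exactly these two forms.

There is no tentative-assignment tier: a sequence is either assigned by
the stated rules or `UNASSIGNED` (with a conflict flag where applicable).
Borderline cases that a human would annotate with a question mark end up
in `Other`, which is retained in per-species totals but excluded from all
group-level inference.

## Synteny evidence and the collision model

Neighbourhoods are extracted by *gene rank*, not base pairs: the bp
windows (200 kb per side by default, expanding to at most 1 Mb in
gene-poor regions) only bound how far the extraction looks, and
`k_genes` (default 2) limits how many neighbours per side are kept.
Strand is recorded but ignored — the adjacency argument is
orientation-agnostic. An empty or one-sided neighbourhood (isolated
contigs, scaffold ends) yields class `undetermined`, never `none`:
missing genomic data must not masquerade as evidence of rearrangement.

Evidence classes are totally ordered: `same_position` (at least one
immediately adjacent neighbour orthologous in both species) beats
`same_chromosome` (a neighbour's ortholog elsewhere on the partner's
chromosome, the signature of an intrachromosomal rearrangement) beats
`none`. The probability that a same-position hit is a chance collision
is `neighbor_slots / genome_gene_count`. The default of four slots (two
immediately flanking genes per side) in a 20,000-gene genome gives
p = 1/5,000 — the worked example that motivates accepting a single
shared adjacent ortholog as proof of synteny. The four-slot reading of
that probability is an interpretation (the narrative form is "one or
more immediately adjacent genes"), so `neighbor_slots` is configurable.
`corroborate()` multiplies the collision probabilities of independent
comparisons (an explicit independence assumption across species) and
tests the product against `alpha` (default 10⁻³).

## Event reconstruction

Presence follows Dollo parsimony — each group arises exactly once and
can only be lost — and copy number follows Wagner parsimony: integer
states, cost |Δ| per branch. Both are solved in a single Sankoff dynamic
program over states 0…S (S = observed maximum + 2, capped at 32) with
the transition parent 0 → child > 0 forbidden (no regain) and an entry
cost |s − 1| at the origin, which deposits one copy. Presence-level
losses are simply transitions to 0. Tie-breaking is deterministic and
conservative: among equal-cost states the smallest ancestral count wins,
which pushes duplication calls as late (towards the leaves) as possible.

Origins come in four flavours:

* `unconstrained` — the branch above the most recent common ancestor of
  the carrying species (the plain Dollo optimum; validated against
  brute-force enumeration of every origin placement in the tests);
* `WGD1` / `WGD2` — the branch carrying that event; the constraint table
  also records the pre-WGD `progenitor` lineage, the post-WGD1 `quartet`
  (at most four WGD2 ohnologs per quartet), and the `paralogon`
  (ancestral chromosome 9 or 16). `pre_WGD` marks a gene already present
  before WGD1 on the same stem;
* `tandem` — a duplication of a named parent group on a named branch,
  optionally ordered `after_event = WGD2` when it shares the WGD stem.

A constrained origin must be ancestral to every species carrying the
group, otherwise reconstruction aborts with an infeasibility error; a
feasible constraint can only add events relative to the unconstrained
optimum (tested as an invariant). Species present in the tree but absent
from the matrix are missing data — no state is forced at their leaves
and no loss is inferred from them. Copy gains on the branch carrying the
teleost-specific WGD are labelled `wgd_retention` when the group predates
that branch; gains of new groups there remain origins.

Two derived quantities deserve their definitions spelled out.
`progenitor_count()` counts distinct pre-WGD lineages: the progenitor
ids of WGD-born groups, with tandem groups collapsing onto their
parent's lineage; without WGD constraints it degenerates to the number
of root-origin groups. `post_wgd_gene_count()` counts genes existing
immediately after WGD2: the repertoire below the WGD2 branch minus
tandem duplicates placed after WGD2 on that stem. On the fixture these
give 3 and 13, with the two post-WGD tandems (BALM, TNFSF-Fish2)
closing the gap to the 15-gene vertebrate-ancestor repertoire.

On the fixture, two groups are left deliberately unconstrained:
TNFSF-New (its relationship to the TNF cluster is uncertain — it may be
a transposed duplicate) and TNFSF-Fish1 (its deep placement is
ambiguous). Their reported origins (teleost and gnathostome ancestors)
are therefore unconstrained Dollo optima, not settled claims. Note also
that the count matrix carries a whale-shark total of 29, which some
narrative summaries round down to 28; the fixture follows the table.

## The simulator: what it emulates, and what it does not

`simulate_history()` starts `n_progenitors` gene lineages at the root
stem and applies, per branch: WGD duplications first (each copy retained
in duplicate with `wgd_retention_prob`; WGD1/WGD2 found new orthology
groups, the teleost-specific WGD adds copies within groups), then
Poisson losses at `loss_rate` and tandem duplications at `tandem_rate`
per copy per unit branch length. Losses act on whole copy lineages;
within-branch churn that cancels (a gain then loss of the same copy) is
collapsed when the truth history is expressed in the reconstruction's
event vocabulary, because no parsimony method could observe it.

Defaults are chosen once as the study conditions: retention 0.8 (2R
ohnologs were retained nearly completely in gnathostomes), loss 0.05 and
tandem 0.02 per gene per unit branch length (slow background turnover,
tandems rarer than losses), rearrangement 0, support noise 0,
3 progenitors, and a 20,000-gene background genome matching the
collision example. Branch lengths default to 1 where the tree carries
none.

`simulate_tracks()` replays the event log over a single scaffold of
1-kb genes spaced 1 kb apart (so the default 200-kb window spans about
100 genes): tandem duplicates insert immediately adjacent to their
parents, WGD duplicates at random positions (a new genomic context), and
each branch applies Poisson(`rearrangement_rate` × length × genes)
random gene moves. `simulate_gene_tree()` emits a tree whose topology
reflects duplication events only — lineages that never duplicate
collapse to polytomies — with supports of 100 minus half-normal noise on
clades whose leaves belong to one group, and 0 on nodes joining
different groups. That support pattern is the generative mirror of the
empirical observation that only within-group branches are statistically
supported in single-domain trees.

What the simulator does *not* model — and hence what passing tests do
not show about real data: sequence evolution (supports are injected, not
estimated, so alignment-length and rate-heterogeneity effects on
bootstrap values are absent), gene conversion between tandem copies,
chromosome fissions/fusions (one scaffold per genome), background gene
birth and death, and assembly artefacts other than the undetermined
class. Homoplasy is modelled but is also the known blind spot of
parsimony: two independent gains on sister branches are reconstructed as
one earlier gain, which is why exact event-list recovery is asserted
only under the no-homoplasy condition (`tandem_rate = 0`), while
repertoire, origin-placement and classification recovery are exact
whenever `loss_rate = 0` and `support_noise = 0`.

## Numerical choices and degenerate inputs

* All randomness flows from a single integer seed; track placement and
  support noise use fixed offsets (+1, +2) of it so each emitter is
  reproducible independently. Identical configurations give
  byte-identical outputs.
* The Sankoff state bound (observed max + 2, ≤ 32) is a documented
  truncation; a bound too small to fit a feasible history raises an
  infeasibility error rather than silently clipping.
* Blank matrix cells are zeros; a stated total ("No." column) is
  recomputed and any mismatch names the offending row. Coordinates are
  0-based half-open; overlapping genes are legal and ordered by start
  then end.
* An all-zero, unconstrained group contributes nothing; a constrained
  group with no surviving copies yields an origin immediately followed
  by a loss on the same branch.
* Single-leaf trees, single-species matrices and empty constraint
  tables are all accepted and degrade to the obvious special cases.

## Validation strategy and problem sizes

The test suite validates each engine against an independent oracle:
Dollo placements against brute-force enumeration of every origin on
1,000 random trees of up to 12 leaves; the Wagner DP against exhaustive
state enumeration on small trees and against phangorn's Sankoff
parsimony (with the origin encoded as an anchor tip of state 1);
neighbourhood extraction against a linear interval scan; the collision
probability against Monte-Carlo placement at 10⁵ draws; and the full
simulate-then-infer loop over 100 seeded replicates plus monotone-trend
checks across loss- and rearrangement-rate grids. Simulated genomes in
the tests use 30–150 background genes — small enough to keep the whole
suite in a few minutes, large enough that neighbourhoods never wrap.

## Known limitations

Reconstruction is parsimony-based: no likelihood model, no dating, no
gene-tree/species-tree reconciliation against topologies, and no
rearrangement-history inference. Constraints are taken as given — the
package checks their feasibility, not their truth. The conservation
summary partitions species by the two clades at the root, which assumes
the root split is the biological contrast of interest (agnathans versus
gnathostomes in the fixture).
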