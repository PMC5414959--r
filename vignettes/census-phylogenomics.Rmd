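---
title: "Census phylogenomics of molecular functions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Census phylogenomics of molecular functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocensus)
```

## The model

`gocensus` treats the genomic abundance of Gene Ontology
molecular-function terms as linearly ordered phylogenetic characters.
The underlying process model has three commitments:

* **Abundance grows with age.** A function that arose early has had
  more time to accumulate variants in genomes, so its per-genome copy
  number and its spread across genomes both increase with age. This is
  what licenses rooting a tree of functions (ToF) with a maximum-state
  hypothetical ancestor.
* **Change is additive.** Between ordered states $i$ and $j$ the cost is
  $|i-j|$ steps (Wagner parsimony): abundance changes by accumulation
  and loss of individual gene copies, not by arbitrary jumps.
* **Distributions are nested (Weston's generality criterion).** The
  taxic distribution of a younger character state should be a subset of
  an older one. Rooting then amounts to finding the direction of
  character change that makes the nesting consistent, which the
  Lundberg procedure tests empirically by attaching the hypothetical
  ancestor at every edge and keeping the most parsimonious placement.

A genome-by-term census is built from annotation (GAF) records: the
abundance $g$ of taxon $t$ in genome $G$ counts the *distinct* gene
products of $G$ annotated to terminal terms in $t$'s constituency. A
gene with two terminal annotations under one taxon counts once; a gene
under two different taxa counts once in each — the DAG's many-to-many
structure is preserved deliberately, because collapsing it would
misrepresent the ontology.

Counts are encoded as 32 ordered states by
$\mathrm{state} = \mathrm{Round}\left(\frac{\ln(g+1)}{\ln(g_{max}+1)} \times 31\right)$,
with $g_{max}$ the matrix-wide maximum. The log damps the huge dynamic
range of abundances (single copies to thousands) and the shared
$g_{max}$ keeps the encoding monotone across the whole matrix, so
$g=0$ is always state 0 and $g=g_{max}$ always state 31. "Round" is
half-away-from-zero (0.5 becomes 1), stated once and applied
everywhere.

## Taxon selection on the DAG

Hierarchy levels are sets of **all** is\_a path lengths from the
namespace root (the root has level 0); a multi-parent term can hold
levels {2, 3} simultaneously and is then analysed at both. Path
enumeration is capped at depth 20 (`term_levels(max_depth=)`), far
beyond the molecular-function DAG's realistic depth, purely to bound
cost on pathological inputs. The four selection rules, applied in
order:

1. a childless term whose levels all lie above level $L$ is promoted to
   be its own taxon at $L$ (annotated childless level-1 terms therefore
   persist through levels 2 and 3);
2. taxa must hold an is\_a route to the root — part\_of- or
   regulates-only children hold no level and their terminals are
   reported as unmapped rather than silently dropped;
3. a taxon with several parents at the level appears once;
4. a taxon holding several levels is retained at each.

"Terminal term" is defined operationally: a molecular-function term
directly assigned to a gene product in a GAF record. Leafness in the
DAG is not required, and gene products annotated directly to
non-terminal levels are excluded from the census. Manual re-assignments
of individual accessions are supported through a user-supplied override
of the mapping rather than hard-coded cases.

## The transfer screen

Horizontally transferred proteins (HTPs) inject homoplasy. Given a list
of HTP gene ids, each terminal term is tested for HTP enrichment among
its annotated gene products against all other gene products with a
one-sided hypergeometric (Fisher) exact test; terms with raw
$p < \alpha$ (default 0.05) are removed. No multiple-testing correction
is applied: the screen is a conservative noise filter, not an
inferential claim about individual terms, and raw $p$ matches the
conventional use of this filter.

## Parsimony machinery

Tree length is computed by the Farris interval pass, vectorised over
characters; an independent Sankoff dynamic program over the full
$32\times32$ cost matrix serves as an oracle in the tests (the two are
checked for equality on a thousand random instances, and against
phangorn's sankoff parsimony). The search is classical: random
addition sequences (default 10) for stepwise addition, then tree
bisection-reconnection to a strict local optimum. TBR reattachment
costs are evaluated with per-edge fold intervals, so a full sweep is
quadratic rather than cubic in taxa. All distinct co-optimal trees
found are kept; where downstream steps need one tree, the first in a
canonical sort of topology strings is used and a strict consensus is
available — an arbitrary but reproducible convention. Bootstrap
replicates draw characters with replacement; a bipartition counts as
recovered in a replicate when it appears in the strict consensus of
that replicate's optimal trees; replicate RNG streams are derived from
the master seed by fixed offsets so results do not depend on execution
order.

Search trees are strictly binary; polytomies arise only via consensus.
Lundberg root ties are broken by the lowest edge index in the canonical
post-order enumeration, and the number of tied placements is reported.

## Timelines

A leaf's depth is the number of internal nodes on the root-to-leaf path
excluding the root; its relative age is $nd = $ depth / maximum depth,
so the basal leaf reads 0 and the deepest reads 1. The divisor is
configurable (`divisor = "n_taxa"` reproduces the older
total-number-of-taxa description), but the printed values in the timeline tables shipped under `inst/extdata/` —
e.g. 0.07 for a depth-1 leaf when the deepest is 14, 0.0096 when the
deepest is 104 — are only consistent with max-depth normalization,
which is therefore the default. Presentation rounding (2 decimals for
levels 1–2, 4 for level 3) is separate from the full-precision values.

The distribution index $f$ is the fraction of in-scope genomes with
$g>0$; Venn groups concatenate the superkingdom letters (A, B, E, in
that order) of genomes carrying the taxon. Age-bin tables use the three
conventional bins 0–0.4, 0.4–0.6, 0.6–1 (half-open except the last).
For the genealogical sorting index the package implements the published
group statistic $gs = (k-1)/\sum_{u}(d_u - 1)$ over the union nodes
connecting the $k$ group members to their MRCA; the binding contract is
$gs = 1$ exactly for monophyletic groups, strictly less otherwise. The
permutation $p$ enumerates all equal-sized leaf subsets when
$\binom{n}{k}$ is small (exact), else samples.

## The synthetic model and what it does (not) show

The generator emulates the process the method assumes: terminal terms
are born in rank order along the **stem line of descent** of a fixed
lineage tree of shape ((A),(B,E)) with a pectinate eukaryal crown —
ALL → BE → E → nested eukaryal subclades. A term is present in the
genomes descending from its birth lineage, minus independent losses
(probability `loss_p`, default 0.05 per genome); its per-genome copy
number is $1 + \mathrm{Poisson}(\lambda (T - r)/T)$ with $\lambda = 5$,
so expected abundance decays linearly with birth rank $r$. Defaults
(40 terminal terms, 30 genomes split 10/10/10 across superkingdoms)
keep a full pipeline run under a minute while leaving enough taxa for
non-trivial topologies. With `hgt_rate > 0` a fraction of terms is
horizontally *mobile*: their genes scatter across lineages irrespective
of ancestry and are labelled HTP with probability `htp_label`; these
mobile terms are the ground-truth target of the transfer screen.

Two honesty notes. First, real annotation data have features the
generator does not emulate: annotation bias across model organisms,
evidence-code heterogeneity, genome-size confounding beyond the log
normalization, and superkingdom-specific *ancient* births. The last is
deliberate: ancient lineage-specific chains converge toward the sparse
(young) end of character space and attach to the tree inverted — the
stem-line model mirrors the empirical observation that ancient
functions are universal, and recovery guarantees simply do not extend
to data violating that nesting. Second, within one birth block adjacent
ranks differ by $\lambda/T \approx 0.125$ expected copies, far below
sampling noise, so the basal taxon of a reconstructed ToF is a member
of the oldest block but not reliably the literal rank-1 term; tests
assert the block-level property, which is what the data can support.

## Numerical choices and degenerate inputs

* All-zero census matrices are an error (the encoding scale is
  undefined), as are genomes without metadata and annotation records to
  unknown or obsolete accessions (warned, skipped and counted).
* Duplicate (genome, gene, term) records collapse to one — evidence
  codes do not multiply abundance. All evidence codes, including IEA,
  are retained.
* Searches on fewer than four taxa return the unique topology; constant
  characters contribute zero steps and leave RI undefined (reported as
  `NA` rather than a conventional value).
* Tie-breaks (co-optimal trees, root placements, hub sorting) are
  always by a stated canonical order, never by memory layout or hash
  order, so runs are bit-reproducible for a fixed seed.

## Problem sizes used in the shipped analyses

The `analysis/` workflow and the test suite run the default synthetic
panel (40 terms × 30 genomes) for end-to-end checks, ten-replicate
addition sequences for final searches, 100 bootstrap replicates for
matrices up to 25 taxa and 25 for larger ones. These sizes were chosen
so a complete desk run of the workflow finishes in minutes while every
qualitative pattern of interest (basal universal taxa, decreasing CI
with deeper levels, late superkingdom-specific terms) is already
expressed.

## Known limitations

* The parsimony search is heuristic: optimality is guaranteed only
  where the tests enumerate exhaustively (≤ 7 taxa).
* GSI's published min–max rescaling is not applied; the statistic is
  reported on its natural (0, 1] scale with the monophyly ⇔ 1 contract.
* The OBO parser covers the OBO 1.2 constructs the pipeline consumes
  ([Term] stanzas, is_a, relationship, alt_id, is_obsolete); it is not
  a general ontology toolkit, and OWL is out of scope.
* Venn groups and $f$ are presence summaries over the sampled genome
  panel; they are not estimates for clades beyond the sample.
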