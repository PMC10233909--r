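---
title: "Methods and design notes for phycoPUL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for phycoPUL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycoPUL)
```

phycoPUL packages the analysis rules of a multi-habitat survey of
seaweed-surface (phycosphere) bacteria: which genera are consistently
part of the community, which gene neighbourhoods equip genomes to degrade
algal polysaccharides, and how genome collections are tiered, dereplicated
and taxonomically reconciled. This vignette explains each model, its
parameters and the design decisions taken where the underlying procedures
left choices open. Everything here is computed by the package's tests or
acceptance script; nothing is quoted from external runs.

## Community classification

The habitat design has four macroalgal hosts (H = *Gelidium* sp.,
R = *Grateloupia* sp., L = *Ulva* sp., B = *Saccharina* sp.) plus seawater
(S) and sediment (N) controls, sampled over four seasons. A taxon
*qualifies* in a habitat when

* it is present in at least `prevalenceMin` (default 0.85) of that
  habitat's samples, and
* it reaches `abundanceMin` percent (default 1.0) in at least one sample.

The category then depends only on the number of qualifying macroalgal
habitats: 4 = core, 3 = dominant, 1–2 = host-specific, 0 = background.
Control habitats are scored with the same rule but reported separately and
never influence the macroalgal category.

Three points were genuinely open and are fixed as follows:

* **Presence** means abundance strictly greater than `presenceFloor`
  (default 0). A detection floor above zero is supported but not default:
  relative-abundance tables have already been denoised upstream (ASV
  inference), so any non-zero entry is treated as a detection.
* **Scope of the abundance condition.** The ≥ 1% condition is evaluated
  *within each habitat* (`abundanceScope = "habitat"`), the stricter and
  more reproducible reading; a `"global"` scope (one loud sample anywhere
  qualifies the taxon wherever it is prevalent) is available as a flag.
* **Seasons are pooled** within a habitat when computing prevalence; the
  alternative (per-season prevalence) would change the denominator and is
  not implemented.

Raising either threshold can only demote a taxon (core → dominant →
host-specific → background); this monotonicity is property-tested.

## Diversity measures

Shannon diversity is reported in nats (natural logarithm), consistent with
the magnitude of values commonly reported for phycosphere samples at the
observed richness; Simpson diversity is the complement form 1 − Σpᵢ², and
Good's coverage is 1 − F₁/N with F₁ the number of singleton taxa. Shannon
and Simpson are computed through `vegan::diversity()`; Good's coverage is
computed directly (no established package exposes it). Expected
rarefaction richness uses the exact hypergeometric closed form
E[S_d] = Σᵢ (1 − C(N−nᵢ, d)/C(N, d)) via `vegan::rarefy()`; the test suite
checks it against a 100,000-draw Monte-Carlo subsampler.

## 16S clustering and cultivability

Only identity thresholds — species 98.7%, genus 94.5%, cultivability
97% — are prescribed by the field's conventions, not an algorithm.
`cluster16S()` therefore adopts UCLUST-style greedy centroid clustering:
items are processed in decreasing neighbour count (ties by input order),
joining the first centroid within the threshold or founding a new cluster.
The testable contract is that every member has at least the threshold
identity to its centroid; this holds by construction and is asserted over
random matrices. Note that the species partition is *not* guaranteed to be
a strict refinement of the genus partition under greedy clustering —
centroid choices differ between thresholds — so no such property is
claimed. A strain matches every ASV at ≥ 98.7% identity (one-to-many
allowed); cultivability is the fraction of ASVs with at least one strain
at ≥ 97%.

## Locus detection

Detection is gene-count based, never bp based: all addressing uses the
0-based `gene_index` in contig order, because the chaining rule is a
sliding window of ten *genes* (`windowGenes`). Two consecutive marker
genes belong to the same locus when fewer than `windowGenes` non-marker
genes lie between them; a gap of exactly ten splits. The boundary is
fixed and tested, and detection is checked for exact equality against a
naive all-pairs transitive-closure oracle on 1,000 random genomes of up to
500 genes (sizes chosen to keep the whole oracle suite within a few
minutes on one CPU).

Marker genes are catabolic CAZymes (classes GH, PL, CE, AA, CBM —
glycosyltransferases are biosynthetic and excluded by default, via
`markerClasses`), plus susC, susD, TonB-receptor and sulfatase genes.
Strand is stored but ignored (`strandAware = FALSE`): conditioning on
strand is not part of the rule set and would silently drop true loci.

Chained candidates are classified by composition:

| category    | rule |
|-------------|------|
| PUL         | ≥ 1 CAZyme and ≥ 1 complete susC–susD pair |
| PUL-like    | ≥ 1 CAZyme and a susC or TonB receptor, no complete pair |
| CGC         | no susC/susD/tonB and ≥ `cgcMinCazymes` CAZymes |
| susCD-only  | ≥ 1 pair, 0 CAZymes |

`cgcMinCazymes` defaults to 3: "CAZyme-rich" is not a number anywhere in
the source procedures, and a single stray CAZyme should not count as a
cluster. Candidates matching no category (a lone sulfatase, one or two
receptor-free CAZymes) are logged in the `dropped` slot, never silently
discarded. A susC adjacent to a TonB annotation is not double-counted:
both act as the receptor role for PUL-like classification.

A *pair* is a susC immediately followed by a susD in gene-index order
(strand ignored; `pairOrientation = "both"` additionally accepts D–C
adjacency). Architectures: `single` (one pair, nothing unpaired),
`tandem_repeat` (consecutive pairs adjacent, …C-D-C-D…), `hybrid` (a pair
plus an unpaired susC or susD), `tandem_repeat_hybrid` (both). Two or
more well-separated pairs with nothing unpaired fit none of the named
shapes and are typed `none`.

**Window monotonicity.** Widening the window can only merge chained
candidates, so the *candidate* count (kept + dropped) is non-increasing in
`windowGenes`. The count of kept loci alone is not monotone — two dropped
one-CAZyme candidates can merge into a valid CGC — which is why the
invariant is stated and tested over candidates.

## PUL composition clustering and substrates

PULs are compared by their ordered CAZyme-family strings (subfamily
labels such as `GH5_2` kept distinct, since subfamilies can differ in
substrate). The dissimilarity is `d = 1 − 2·LCS(a,b)/(|a|+|b|)` over the
longest common subsequence of family labels. The clustering procedure
this emulates is specified only through its cut — grouping *identical*
compositions — and any dissimilarity with d = 0 ⇔ identical strings
reproduces that behaviour; LCS additionally gives a graded notion of
partial similarity for non-zero cuts (single linkage via `stats::hclust`).
The distance is a symmetric premetric with d(x,x) = 0; the triangle
inequality is *not* asserted, as LCS-based dissimilarities can violate it.

Substrate inference is a rule engine over compositions
(`inst/extdata/substrate_rules.yaml`, editable). Each rule lists required
family groups (all groups must be satisfied; within a group any family
suffices), an optional exclusivity constraint and a minimum sulfatase
count. Where a mapping was stated as a pair of markers (GH3+GH16,
GH13+GH65) each marker is its own required group (both needed); where it
was stated as a family list (PL6/PL7/PL12/PL17; CE1/CE3/CE4; PL25/PL40;
GH29/GH106) the list is one any-of group. Subfamilies match their parent
family at rule-evaluation time. All satisfied rules fire, so large loci
may receive several substrates. Sequence-tree-based substrate assignment
(SusC/D protein phylogenies) is deliberately out of scope — it requires
alignments — and the rule layer is the composition-only replacement.

## Genome quality, dereplication, taxonomy

Quality tiers are evaluated in fixed order: `high` (completeness ≥ 90,
contamination < 5, complete rRNA operon, ≥ 18 tRNAs — the MIMAG
high-quality bar), else `nearly_complete` (completeness > 90,
contamination < 5), else `medium` (completeness ≥ 50, contamination < 10,
the retention floor), else `reject`. Note the deliberate asymmetry at
completeness = 90: with full rRNA/tRNA extras it is `high`, without them
it is `medium`, because the nearly-complete tier is defined with a strict
inequality.

Species clusters are the connected components of the graph with an edge
at ANI ≥ 95% and aligned fraction ≥ 0.65. Components were chosen over
greedy secondary clustering because they are deterministic and
order-free, hence directly testable against a union-find oracle; the
within-cluster non-redundant set is built greedily in decreasing score
order (score = completeness − 5 × contamination, the dRep default) so
that no two retained genomes share ≥ 99% ANI. Representatives are the
top-scoring member (ties by genome id) and are always part of the
non-redundant set.

Taxonomy reconciliation walks ranks from domain to species: unanimity is
accepted; with ≥ 3 sources a value shared by ≥ 2 wins (flagged
`majority`); a two-source disagreement is resolved toward GTDB — the
primary classifier — and flagged, or left unresolved with
`prefer = "none"`, truncating the lineage at the previous rank. Output
lineages are always rank prefixes (no genus without a family). The
original no-16S special case ("take SILVA when SILVA and GTDB agree") is
self-contradictory as written — when they agree there is nothing to
choose — so the implemented rule (agree → accept, disagree → GTDB + flag)
is a documented interpretation; the `has_16s` flag is carried for
provenance only.

## Synthetic data: what it does and does not emulate

The generators produce inputs whose *planted truth is enforced, not just
expected*: a sample or genome that would violate its planted label is
resampled, so recovery tests demand 100% precision and recall rather than
a probabilistic bound.

* `simCommunity()` defaults plant 14 core + 14 dominant genera across
  four habitats with 12 samples each (four seasons × three replicates),
  mean qualifying abundance 3% (s.d. 1.5), dropout probability 0.05 —
  safely below the 0.15 infeasibility bound implied by the 85% prevalence
  threshold. Columns renormalize to 100 whenever the planted mass
  supports it; sparse plantings (e.g. zero core taxa) are left as
  partial-community columns so background taxa are not inflated past the
  1% threshold by renormalization alone.
* `simAnnotatedGenome()` writes planted loci verbatim, padding each by at
  least `windowGenes` plain genes, and sprinkles isolated background
  CAZymes at least a window away from everything, so planted spans can
  never merge and recovery is exact by construction.
* `simANIMatrix()` draws within-species ANI from U(96, 100) (AF ≥ 0.7)
  and between-species ANI from U(75, 93), leaving a wide margin around
  the 95% threshold.
* `simIdentityMatrix()` separates matched pairs (≥ 98.7%) from the
  unmatched bulk (< 96%) by a full point below the 97% cultivability
  threshold.

What passing these tests shows is that the *rules are implemented
exactly*; it does not show robustness on real data. The generators do not
emulate compositional correlation between taxa, seasonal trends, chimeric
or contaminated bins, borderline ANI values near the species threshold,
or loci whose markers straddle contig breaks — all of which occur in real
surveys and will blur any threshold-based rule.

## Numerical choices and problem sizes

Determinism comes solely from integer seeds (`set.seed`); no locale or
time dependence. Symmetry of identity/ANI matrices is required within
1e-9; CAZyme density equality within 1e-9 in the container validity.
Degenerate inputs error loudly: all-zero count vectors, rarefaction
depths above the total, asymmetric matrices, samples without metadata,
malformed family labels (with line numbers), genomes without quality
records. Test problem sizes — 1,000 random genomes of 50–500 genes for
the detection oracle, 20 community seeds, 50 genome seeds, 100,000
Monte-Carlo rarefaction draws — were chosen to exercise every branch
while keeping the full suite in the low minutes on a single CPU.

## Known limitations

* The window semantics ("fewer than ten intervening genes") is a
  documented operationalization; bp-distance windows are intentionally
  not offered.
* Greedy 16S clustering depends on processing order where identity
  structure is ambiguous; only the member-to-centroid contract is
  guaranteed.
* Substrate counts from composition rules are not comparable to
  pipelines that add protein-tree evidence or curated PUL-database hits;
  the rule table is a transparent, editable lower bound.
* Upstream steps (assembly, binning, HMM annotation, ANI computation,
  tree building, ordination) are consumed as inputs, never recomputed.
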