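---
title: "Delineating possible groups of orthologs and counting founder genes"
author: "PoGOfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating possible groups of orthologs and counting founder genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plant gene families — here exemplified by the xyloglucan-modifying
enzymes of the primary cell wall, and above all the xyloglucan
transglycosylase/hydrolases (XTH) — expand and contract by gene
duplication and loss as lineages diverge.  To say when an enzymatic
activity arose ("before land colonization", "in the last common ancestor
of seed plants") one needs to partition today's family members into
*possible groups of orthologs* (PoGOs): supported gene-tree clades each
standing for one ancestral *founder gene*.  Counting the PoGOs
represented in successively younger lineages then traces the family's
growth along the green-plant ladder, and the pattern of presence and
absence of each PoGO across complete genomes localizes gains and losses.

PoGOfam implements that procedure end to end: homolog harvesting from
proteomes and six-frame-translated ESTs, distance-based phylogenies with
nonparametric bootstrap, PoGO delineation on the rooted gene tree,
founder counting and Dollo-parsimony gain/loss inference — plus a
birth–death simulator that generates families with *known* orthology so
the whole chain can be validated without any external data.

## Homology harvesting

Queries (characterized family members) are compared against every
proteome with exhaustive Smith–Waterman local alignment under BLOSUM62
with affine gaps 11/1 (a gap run of length $L$ costs
$11 + (L-1) \cdot 1$).  Significance uses the Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ with the published gapped BLOSUM62-11/1
constants ($\lambda = 0.267$, $K = 0.041$); hits with $E > 10^{-4}$ are
discarded.  Because the engine is exact dynamic programming rather than
a word-seeded heuristic, no hit below the cutoff can be missed; the
`seed_word_length` field of `scoringConfig()` is retained for interface
completeness but the engine does not consult it.  E-values here serve as
a cutoff, not as a reproduction of NCBI statistics (no composition-based
adjustment, no low-complexity masking); standard 12-column BLAST
tabular files are accepted as a drop-in alternative input.

EST evidence is mined by searching all six translation frames
(`sixFrameTranslate()`: codons from offsets 0–2 of each strand, partial
trailing codons dropped, ambiguous codons rendered `X`, stops `*`).  For
each retained EST the subject-side aligned blocks are concatenated in
ascending nucleotide coordinate into one protein record (overlapping
same-frame blocks merged); ESTs whose hits cover less than 40% of the
query are excluded, the boundary being inclusive at exactly 40% because
the rule is stated as "less than 40% excluded".  Within each species,
records at $\ge 99\%$ global-alignment identity (matches over the
shorter sequence's length) collapse to their longest member — an
automated, configurable stand-in for what is normally manual
isoform curation.  Cross-species records never merge.

## Alignment and trees

The progressive aligner builds pairwise global alignments, converts them
to p-distances, infers a neighbor-joining guide tree and merges profiles
leaf to root with the same affine scoring (profile columns are scored by
frequency-weighted substitution scores; the gap symbol scores zero and
gap placement is charged through the affine penalties).  Tie-breaking in
the dynamic program is fixed (match preferred, then a gap in the first
profile), so alignments are deterministic.  De-gapping any row always
reproduces its input sequence.  No column trimming is applied by
default; `trimAlignment()` offers an occupancy filter.  Externally
computed alignments can be supplied as aligned FASTA.

Distances are the p-distance (proportion of differing residues among
compared positions) and the PAM-001 correction.  Gap handling is
pairwise deletion — a column is compared for a pair only when both rows
carry an unambiguous residue — because EST-derived rows are fragmentary
and complete deletion would waste most columns.  The PAM distance is
defined literally from the Dayhoff model: with $M$ the PAM1 transition
matrix and $\pi$ its stationary composition, the expected proportion of
observed differences after $D$ PAM units is
$p(D) = 1 - \sum_a \pi_a [M^D]_{aa}$, and the reported distance is the
$D$ (in substitutions/site, $D/100$) solving $p(D) = p_{\text{obs}}$ by
monotone bisection to $|\Delta p| \le 10^{-9}$, capped at $D = 1000$.
The rate matrix comes from the Dayhoff model tables shipped with
phangorn; one PAM unit is calibrated so $p(1) = 1\%$ exactly, and $M^D$
for real $D$ is evaluated in the eigenbasis.  Observed $p$ beyond the
asymptote $1 - \sum_a \pi_a^2$ raises a saturation error rather than a
silent cap.

Neighbor joining follows the canonical Saitou–Nei agglomeration with two
determinism guarantees: ties in the $Q$ criterion (within $10^{-12}$
relative) break by the lexicographic order of cluster labels, and
negative branch lengths are clamped to zero with the deficit moved to
the sister edge.  On an additive matrix the generating topology and all
branch lengths are recovered exactly (property-tested against an
independent implementation).

Bootstrap supports attach to the bipartitions of the full-data tree, not
to a consensus, matching how support values are displayed on a single
topology: columns are resampled with replacement (seeded generator, so a
seed fully determines the annotated tree), each replicate tree is built
with the same distance/builder, and each internal edge is labelled with
the rounded percentage of replicates containing its bipartition.  A
replicate whose resampled columns saturate a distance is re-drawn and
counted.  Internal edges of length zero carry no distance signal — an
all-zero matrix is resolved arbitrarily (if deterministically) — so
their support is reported as 0 rather than a spurious 100.  Rooting uses
a designated outgroup (in the motivating analyses, fungal homologs),
placed on the edge separating it from the ingroup; a non-monophyletic
outgroup is an error naming the intruding leaves.

## PoGO delineation

A clade of the rooted, support-annotated gene tree is accepted as a PoGO
when three criteria hold:

1. **Support.** Bootstrap support strictly greater than 50 (missing or
   unresolved labels count as 0 — conservative).
2. **Anchoring.** The clade contains at least one gene from a reference
   species with a complete, well-annotated genome (defaults: *At*, *Os*),
   **or** it is lineage-restricted: all members fall within one proper
   lineage-tree node's subtree and at least two distinct species are
   represented.  "One lineage" is operationalized as any non-root node
   of the lineage tree, because published lineage-restricted groups span
   e.g. a streptophyte alga plus a liverwort — confined to Streptophyta
   but not to a single named class.
3. **Species consistency.** The clade must not contradict the species
   phylogeny.  This is the one criterion that is a judgement call in the
   original procedure, and it is operationalized here as a two-part
   test (`checkSpeciesConsistency()`):
   (a) no species contributes more than `max_copies` (default 3) leaves —
   within-group tandem paralogy is real, but many copies of one species
   indicate a super-group;
   (b) every internal edge with support above 50 splits the clade's
   species into two sides: if the sides share **two or more** species the
   edge implies a duplication ancestral to several species, i.e. the
   clade spans more than one ortholog group, and it is rejected; if the
   sides are disjoint, the implied species bipartition must be
   compatible with the lineage tree (polytomies resolve freely); exactly
   one shared species — a tandem pair straddling the edge — is
   tolerated, as is any conflict on a weakly supported edge.

   An earlier candidate operationalization (prune the clade to one
   representative per species and test only the pruned topology) was
   rejected during design: pruning erases exactly the duplication
   signature that must cause rejection when a clade contains two copies
   of the same species *pair* on well-supported sister subclades.

Accepted clades are maximal: a pre-order scan accepts the shallowest
passing node on each root-to-leaf path and never descends into an
accepted clade, matching a largest-groups-first reading of collapsed
clade displays.  Outgroup leaves are excluded throughout.  Left-over
leaves that form supported single-species clades become *paralog
groups*; everything else stays unassigned.  Each PoGO's *origin* is the
MRCA, on the lineage tree, of its member species.

## Founder counts and Dollo gains/losses

Founder arithmetic in the literature mixes two counting rules, so both
are always computed (`founderProfile()`):

* `founder_count(node)` — PoGOs with at least one member species inside
  the node's subtree (containment).  This reproduces the ladder counts
  2 (streptophyte algae, a two-node grade counted as a union), 7
  (Lycophyta step) and 18 (angiosperms) on the shipped XTH worked
  example.
* `shared_count(node)` — PoGOs with members both inside and outside the
  node.  This reproduces the "five in early embryophytes" figure: the
  moss sits in six PoGOs, but the moss-restricted one represents no
  lineage-spanning founder.

Neither rule is silently preferred; the reports print both.  Under a
loss-free process the shared count is monotone non-decreasing along any
nested root-to-tip ladder (property-tested on simulations); the
containment count is not, precisely because of lineage-restricted
gains.

Gain/loss inference is Dollo parsimony (`dolloGainLoss()`): the gain is
the lineage-tree MRCA of the members; losses are the unique minimal
antichain of maximal branches whose subtrees contain no member but at
least one *complete-genome* species.  Species represented only by ESTs
can attest presence but never absence, so they are uninformative for
losses and may sit silently under a loss branch.  Every call replays the
inferred events and verifies that they reproduce the observed
presence/absence over complete genomes exactly; minimality is verified
in the test suite against exhaustive enumeration over loss subsets.

## The simulator: what it emulates and what it does not

`simConfig()` defaults define the validation conditions, chosen once to
resemble a desk-scale version of a green-plant family survey:

* an ultrametric species tree of depth 0.4 time units with an
  eight-species ingroup (two four-species subfamilies standing for,
  e.g., eudicots and monocots) and a two-species outgroup — two leaves,
  because a single-leaf outgroup would make the ingroup's stem
  bipartition trivial and unsupportable;
* duplication rate 0.1 per branch-length unit, loss rate 0, one root
  lineage; duplications copy a single gene lineage in place (no
  whole-genome duplication mode);
* 400 codons; sequences evolve at *codon* level — uniform sense-codon
  root, Poisson nucleotide substitutions at 0.3 per site per unit
  (substitutions creating internal stops are redrawn), optional
  whole-codon indels (off by default) — so that EST fragments and
  six-frame translation are exercised honestly rather than on protein
  strings;
* EST emission for a quarter of the genes: one contiguous codon window
  of geometric-tailed length (mean 150 codons), random strand, per-base
  error 0.005.

These rates give well-supported true clades (tens of substitutions per
internal edge over 400 codons) without saturating the deepest pairwise
comparisons.  Everything is a pure function of `(config, seed)`; truth
labels (the orthogroup partition obtained by cutting the gene tree at a
reference ancestor, by default the ingroup MRCA) live in separate
outputs that the pipeline under test never reads.

What passing the recovery benchmark shows — and what it does not: the
simulator produces clock-like, composition-homogeneous, indel-free
families with complete proteomes.  Real families violate all of these
(rate heterogeneity across sites and lineages, biased codon usage,
domain-level events, annotation gaps), so the ≥ 90% end-to-end recovery
under the default conditions demonstrates the *logic* of the chain, not
field accuracy.  One failure mode is structural and expected: when a
duplication occurs on an internal branch ancestral to two or more
species, the calling criteria split the two copies into separate groups
(as the published criteria do), while the truth cut at the ingroup
ancestor keeps them in one orthogroup.  With the default rates such
events hit roughly 4–6% of families, which bounds recovery away from
100% by design rather than by estimation error.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package;
  conversion to 1-based inclusive happens only at the BLAST-tabular
  boundary.
* Newick serialization is canonical (children ordered by smallest
  descendant leaf; `%.12g` lengths), so equal trees serialize
  identically and round trips preserve lengths to $10^{-10}$.
* Two-taxon distance matrices yield the single edge split evenly across
  the two pendant branches; three taxa use the closed form.
* Empty sequences are legal in pairwise alignment (an all-gap row with
  the affine run cost); empty FASTA files yield empty sets; an empty
  simulated family (all lineages extinct) is flagged and redrawn from a
  derived seed.
* Duplicate record ids, non-symmetric distance matrices, unrooted input
  to the caller, unregistered species and scattered outgroups all fail
  fast with named offenders.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `evalue_max` | 1e-4 | Karlin–Altschul cutoff for reporting a hit |
| `gap_open`, `gap_extend` | 11, 1 | affine penalties, BLOSUM62 units |
| `min_fraction` (coverage) | 0.40 | minimum query coverage for ESTs, inclusive |
| `identity_threshold` (collapse) | 0.99 | within-species redundancy threshold |
| `min_support` | 50 | PoGO support, strictly exceeded |
| `conflict_support` | 50 | consistency test ignores weaker edges |
| `max_copies` | 3 | per-species copy bound within one PoGO |
| `n_replicates` | 1000 | bootstrap replicates (100 in the validation runs, to keep the suite fast at unchanged conclusions) |
| `reference_species` | At, Os | anchoring genomes for criterion 2 |

## Known limitations

* Maximum-likelihood tree inference is out of scope; an externally
  computed ML tree in newick (supports as node labels) can be fed
  directly to `callPogos()`.
* The e-value model ignores composition adjustment, so absolute
  e-values near the cutoff can differ from other search engines even
  though scores are exact.
* Reconciliation-based orthology and synteny evidence are not used;
  duplication/loss mapping exists only on the simulator's truth side.
* The lineage tree treats the streptophyte algae classes as a grade
  directly under Streptophyta; an alternative nesting can be supplied
  through the registry's lineage paths.
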