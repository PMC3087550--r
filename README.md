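# PoGOfam

Ortholog-group delineation and founder-gene inference for green plant
gene families.

## What this is for

Comparative surveys of plant gene families — the motivating case is the
xyloglucan-related cell-wall machinery, whose largest family is the
xyloglucan transglycosylase/hydrolases (XTH) — ask *when* each enzymatic
activity arose: in the streptophyte algae before land colonization, in
the first embryophytes, in the seed-plant ancestor.  Answering that
requires partitioning the extant family into **possible groups of
orthologs (PoGOs)**: clades of a bootstrap-annotated gene tree that
(1) are supported above 50%, (2) contain a gene from a reference genome
(*Arabidopsis thaliana* and/or *Oryza sativa*) or are confined to one
lineage with at least two species, and (3) do not contradict the known
species phylogeny.  Each PoGO shared between lineages stands for one
**founder gene** in their common ancestor, so counting PoGOs along the
lineage ladder (streptophyte algae → bryophytes → lycophytes →
angiosperms) traces the family's expansion, and Dollo parsimony over
presence/absence in complete genomes localizes the losses.

PoGOfam implements the full chain for R users, in Bioconductor style
(Biostrings sequence sets, ape trees, S4 result classes):

* homolog harvesting: exact Smith–Waterman search of protein queries
  against proteomes and six-frame-translated ESTs, Karlin–Altschul
  e-value cutoff (1e-4), aligned-block extraction for EST hits, a 40%
  query-coverage filter, and within-species redundancy collapse;
* multiple alignment: a deterministic progressive aligner (NJ guide
  tree, affine profile merging), or externally supplied aligned FASTA;
* phylogenies: p-distance and PAM-001 (Dayhoff) distances with pairwise
  deletion, neighbor joining with exact recovery on additive matrices,
  seeded nonparametric bootstrap, outgroup rooting, canonical newick
  I/O;
* PoGO calling, founder-count profiles (containment and shared modes),
  and Dollo gain/loss inference aware of EST-only species (which can
  attest presence but never absence);
* a birth–death gene-family simulator with known orthology truth, so
  the entire pipeline is testable end to end with no downloads;
* `runPipeline()`: one-call orchestration with YAML config, structured
  logging and a hash-bearing run manifest.

## Worked example

The package ships the species registry and published group memberships
of the green-plant XTH family as plain TSV.  Founder counts along the
ladder:

```r
library(PoGOfam)
reg <- xthSpeciesRegistry()
pogos <- xthPogoFixture()
founderProfile(pogos, reg, xthLineageLadder())[, 1:3]
#>                                            node founder_count shared_count
#> streptophyte_algae  Charophyceae+Zygnemophyceae             2            2
#> early_embryophytes                    Bryophyta             6            5
#> early_tracheophytes                   Lycophyta             7            7
#> angiosperms                         Angiosperms            18            9
```

Two founder genes in the streptophyte algae, seven by the early
tracheophytes, eighteen in the angiosperms; the moss sits in six groups
but only five are shared beyond the bryophytes — the shared count is
the founder-gene reading.  Loss inference for a group present in moss,
lycophyte and all four eudicot genomes but absent from both monocot
genomes:

```r
dolloGainLoss(c("Pp", "Sm", "At", "Gm", "Pt", "Vv"), reg)
#> $gain
#> [1] "Embryophyta"
#> $losses
#> [1] "Monocots"
#> $n_losses
#> [1] 1
```

— gained in the embryophyte ancestor, lost once on the monocot stem.
Calling groups on a tree works directly from newick:

```r
tr <- readNewick("((At_1:.1,Os_1:.1)90:.1,(At_2:.1,Os_2:.1)85:.1)99;")
reg2 <- SpeciesRegistry(data.frame(
  species_code = c("At", "Os"),
  full_name = c("Arabidopsis thaliana", "Oryza sativa"),
  lineage_path = c("Viridiplantae;Angiosperms;Eudicots",
                   "Viridiplantae;Angiosperms;Monocots"),
  genome_complete = TRUE))
callPogos(tr, reg2)
#> PoGOSet: 2 PoGOs, 0 paralog group(s), 0 unassigned leaf/leaves
#>  pogo support      origin n_members n_species
#>     A      90 Angiosperms         2         2
#>     B      85 Angiosperms         2         2
```

The 99% clade is *not* one group: both reference species appear twice
on well-supported sister subclades, the signature of a duplication
ancestral to both — so the caller splits it.

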