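# caspevo

Comparative evolutionary analysis of the inflammatory caspase gene locus.

The caspase-1 subfamily — caspase-1, its tandem paralogs caspase-4/-5
(caspase-11 in rodents), caspase-12 and the CARD-only genes — sits in one
syntenic locus whose history in primates and rodents is a churn of
duplication, pseudogenization, whole-gene loss and gene conversion, with
episodes of positive selection layered on top. caspevo is an R package for
researchers in molecular evolution and innate immunity who want to
reconstruct that history from genome sequences: it turns per-species locus
sequences plus a reference gene layout and a species tree into gene-status
calls, conversion-tract maps, gain/loss reconstructions, selection scans,
cleavage-site conservation reports and inbred-strain variant
classifications — and ships a locus evolution simulator with a complete
truth log so every stage is validated against data whose generating
history is known exactly.

## What it computes

* **Exon annotation** — seeded Smith–Waterman search for reference exons
  (identity ≥ 60%, bit score > 100, both strands), synteny-based
  assignment of hits to paralog slots, in-frame CDS assembly.
* **Gene status** — the four-way call per homolog: *present* (lesion-free,
  full-length), *partial in-frame*, *pseudogene* (frameshift indels,
  premature stops, exon loss), *absent* (< 70% of reference exons), with
  cross-species lesion corroboration and assembly-error flags.
* **Duplication / conversion tracts** — intra-locus self-similarity blocks
  (≥ 1 kb, ≥ 50% identity, both orientations) via seed–chain–score, and
  clade-level gene-conversion events from paralog-tree intermixing:
  conversion is called for species *s* and paralogs *g, h* when
  d(g_s, h_s) < min over species t of d(g_s, g_t) (Jukes–Cantor).
* **Gain/loss histories** — single-gain (Dollo) parsimony: origin at the
  MRCA of intact species, losses as the minimal branch set (one per
  maximal non-intact clade); duplication dating from node ages in Mya.
* **Selection** — Nei–Gojobori (NG86) pairwise dN/dS with minimal-pathway
  averaging and Jukes–Cantor correction; dS ≤ 0.3 species filtering;
  alignment splitting at recombination breakpoints; a SLAC-style site
  scan on Fitch-reconstructed substitutions, testing each site's
  nonsynonymous count against a neutral expectation scaled from the
  segment-wide synonymous rate, with Bonferroni-level (3.33e-3)
  segment tests and robustness re-runs across settings.
* **Cleavage sites** — conservation of the three aspartate self-cleavage
  sites (CARD–p20, p20–linker, linker–p10), with nearby-alternate-D
  search (± 5 residues).
* **Strain variants** — the three-way conservation rule (*potential
  impact* / *unlikely* / *unknown*), strain avoid/caution/clean reports,
  and detection of frame-restoring variants that expose reference
  assembly errors. Transcriptions of the published mouse (16 strains) and
  rat (8 strains) variant tables ship under `inst/extdata/tables/`.

## Worked example

Simulate a six-species locus with a scripted caspase-12 loss and a
caspase-5 pseudogenization, then run annotation, status calling and Dollo
reconstruction:

```r
library(caspevo)
tr <- ape::read.tree(text =
  "(((A:0.03,B:0.03):0.03,(C:0.03,(D:0.02,E:0.02):0.02):0.02):0.02,F:0.08);")
cfg <- simConfig(tr, defaultLayout(intergenicLen = 3000L, intronLen = 800L),
                 events = list(
                   list(kind = "loss", branch = "A", gene = "casp12"),
                   list(kind = "pseudogenize", branch = "D,E",
                        gene = "casp5")),
                 seed = 7L)
sim <- simulateDataset(cfg)
res <- runPipeline(sim, stages = c("status", "events"))
res$summary$statusCounts
#> $absent
#> [1] 1
#> $present
#> [1] 39
#> $pseudogene
#> [1] 2
res$events[res$events$gene %in% c("casp5", "casp12"), ]
#>          gene lossCount  originTips lossBranches
#> casp5   casp5         1 A,B,C,D,E,F          D,E
#> casp12 casp12         1 A,B,C,D,E,F            A
```

The 42 status calls (6 species x 7 genes) recover the scripted history
exactly: the one *absent* call is caspase-12 in species A, the two
*pseudogene* calls are caspase-5 in D and E, and the Dollo reconstruction
reports each scripted event as a single loss on the correct branch — one
on the terminal branch to A, one on the stem of the (D,E) clade.

The strain report runs directly from the bundled tables:

```r
v <- readVariantTable(system.file("extdata/tables/table3_mouse.tsv",
                                  package = "caspevo"))
rec <- recommendStrains(v[v$gene != "none", ], c("casp11", "casp12"),
                        allStrains = unique(v$strain))
table(rec$flag)
#> avoid caution   clean
#>     8       1       7
```

Half of the 16 mouse lines carry caspase-11/-12 variants with potential
or untested impact (the *avoid* set), one carries only variants whose
alternate residue occurs in other rodents (*caution*), and seven are
variant-free in these genes.

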