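---
title: "Methods: models, tests and design choices in caspevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, tests and design choices in caspevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspevo)
```

# Scope

caspevo reconstructs the evolutionary history of a multi-gene
inflammatory-caspase locus across a panel of mammal species. The pipeline
takes per-species locus sequences, a reference gene layout and a species
tree, and produces: exon annotations and assembled coding sequences;
four-way gene status calls (present / partial in-frame / pseudogene /
absent) with lesion evidence; intra-locus similarity blocks marking
segmental duplications and gene-conversion tracts; clade-level gene
conversion calls from paralog-tree intermixing; Dollo parsimony gain/loss
reconstructions with duplication dating; a recombination-aware,
counting-based selection scan; aspartate cleavage-site conservation
reports; and conservation-based classifications of inbred-strain missense
variants. A codon-level locus simulator with a complete truth log is a
first-class component: every stage is validated against data whose
generating history is known exactly.

# The simulator

`simulateDataset()` builds a random ancestral locus from a configurable
layout (seven genes in syntenic order by default: two tandem protease
paralogs, a central protease flanked by three CARD-only genes and a distal
protease; exons 150-300 bp, introns ~1.2 kb, intergenic spacers sized so
the default locus is roughly 350 kb) and evolves it down a species tree.

**Substitution model.** Non-coding DNA evolves under HKY (kappa = 4 by
default, uniform base frequencies), applied per branch through the exact
transition-probability matrix. Coding DNA of intact genes evolves under a
codon jump process: each codon's single-nucleotide neighbors get rate
proportional to the HKY weight of the change, multiplied by the site's
omega when the change is nonsynonymous; changes creating stop codons are
disallowed, and the start and terminal stop codons are held fixed (a
stochastic lost start or lost stop would silently contradict the status
truth log). Rates are scaled so a neutral site accrues one expected
substitution per nucleotide per unit branch length. Multiplying the
*nonsynonymous* rate by omega represents both purifying (omega < 1) and
positive (omega > 1) selection; an acceptance-rejection scheme capped at
probability one could not represent omega > 1 at all, which is why the
rate parameterisation was chosen. Pseudogenized and truncated genes drop
to the neutral nucleotide model from the moment of their lesion.

**Structural events are scripted, not drawn.** Each event names its branch
(the branch above the MRCA of the listed species), so the truth log is
exact: whole-gene deletion, pseudogenizing lesions (frameshift indels,
premature stops), terminal-exon truncation (partial in-frame genes),
tandem duplication (the gene plus ~1.5 kb flanks reinserted immediately
downstream), intergenic segmental insertion, and gene conversion.

**Gene conversion is modeled as concerted evolution.** A conversion event
overwrites the acceptor gene's tract with the donor's sequence at the
midpoint of its branch and is then re-applied midway along every
descendant branch. This recurrence is not an implementation convenience
but a logical requirement of the detection rule (next section): after a
single ancient overwrite, the within-species paralog distance is at least
the distance to the nearest ortholog for every species inside the
converted clade, in expectation, so a one-off conversion deep in the tree
is undetectable by distance comparisons. Ongoing homogenization is also
what the biology of interest looks like: the tracts stay similar because
conversion keeps recurring.

**What the simulator does not model**, and hence what passing tests do not
demonstrate about real data: insertions/deletions outside scripted events
(real alignments need indel handling the annotation stage only meets
through its gapped local alignments); transposon families (segmental
insertions are sequence-agnostic); assembly errors and base-calling noise;
rate variation among lineages beyond branch lengths; and biased gene
conversion. The recovery statistics (exon F1, status agreement) are
therefore upper bounds on real-data performance.

# Exon annotation and gene status

Exons are located by exact 12-mer seeding followed by local
Smith-Waterman alignment of the seeded windows (match +1, mismatch -2,
gap open -2, extend -1; BLASTN-style bit scores with lambda 0.625,
K 0.41). A hit must reach 60% identity (gap columns count as mismatches)
and 100 bits; both strands are searched; hit intervals are extended across
unaligned exon ends so terminal mismatches do not truncate the interval.
With this scoring, local alignments below roughly 60% identity have
negative expected score and do not exist, so the 60% identity floor and
the seed-based sensitivity limit coincide comfortably.

Hits are clustered along the locus (gap threshold above the largest
intron, below the smallest intergenic distance) and clusters are matched
to the reference syntenic slot order by a dynamic program maximizing
summed bit score over non-decreasing slot assignments. Slot reuse (tandem
duplicates) carries an infinitesimal penalty so distinct slots win ties,
and a smaller bias prefers the upstream slot — the documented tie-break
for a hit equidistant between two slots. Within a cluster each reference
exon index is filled by the best hit, preferring hits labeled with the
assigned gene but accepting cross-paralog labels (synteny rescue).

Status calls follow a fixed decision order: fewer than 70% of reference
exons gives *absent*; otherwise a lesion-free CDS aligning over at least
95% of the reference length is *present* (the 95% tolerance absorbs
terminal codon variation); a lesion-free but shorter in-frame span is
*partial in-frame*; anything else is *pseudogene*. Frameshifts are indels
with length not divisible by three in the global alignment to the
reference CDS; in-frame stops upstream of the reference stop are
premature stops; a missing ATG is a lost start. *Internal* missing exons
are exon-loss lesions, but *terminal* missing exons are treated as
truncation evidence, not lesions — otherwise every partial in-frame gene
would be classified a pseudogene and the four-way scheme would collapse
to three categories. Lesions found at homologous coordinates in at least
one other species are marked corroborated; singletons are flagged
low-confidence (candidate assembly errors), and the companion
`detectFrameRestoration()` identifies the converse pattern where every
resequenced strain repairs a frameshift carried by the reference
assembly.

# Similarity blocks and conversion calls

`findSimilarityBlocks()` is a seed-chain-score detector: exact 12-mer
self-matches (k-mers occurring more than 64 times are skipped), chained
along diagonals with a 200 bp gap limit, merged when their interval pairs
overlap, then scored by global alignment of the two intervals. Reported
blocks are at least 1 kb long at 50% identity or better, in both direct
and inverted orientation, with the self-diagonal excluded. Exact seeding
bounds sensitivity: a 12-mer survives at per-base identity p with
probability p^12, so tracts below ~70% identity are effectively
invisible even though the reporting floor is 50%. The planted-tract tests
therefore use 85-100% identity, the regime recent conversions occupy.

Conversion calls from sequence trees use the within-species test: for
species s and paralogs g, h, a call is made when the Jukes-Cantor
distance d(g_s, h_s) falls below the minimum cross-species within-gene
distance for either gene. Called species are merged into the minimum
number of clade-level events (each maximal fully-called clade counts
once). Saturated distances (JC undefined) are treated as infinitely far,
which is the correct behaviour for ancient paralogs.

# Dollo reconstruction and dating

Genes are assumed to arise once (single-gain / Dollo): the origin is the
MRCA of the intact species and the losses are one per maximal all-non-
intact clade within the origin clade, which is provably the minimum
branch set. Pseudogene, partial and absent all count as non-intact for
event counting, so "pseudogenization and/or loss" events are counted
uniformly. Duplications are dated to the interval between the origin
node's age and its parent's age; a duplicate present in all leaves is
reported open-ended above the root. Node ages are inputs (literature
divergence times), supplied as a side table keyed by internal node
labels, never estimated.

# The selection scan

Pairwise dN/dS uses Nei-Gojobori counting: per-codon synonymous site
fractions (changes to stops excluded from the mutational opportunity),
differences averaged over all minimal mutational pathways avoiding stop
codons, Jukes-Cantor correction, with saturation (p >= 3/4) reported
rather than silently clamped. The implementation's precomputed pathway
tables are checked exactly against an independent recursive enumeration
over all 61 x 61 sense-codon pairs in the test suite. Species are
filtered at pairwise dS <= 0.3 to the reference before multi-species
scans, and alignments are split at externally supplied recombination
breakpoints (nucleotide positions snapped to the nearest codon boundary,
snaps reported), each segment analyzed independently.

The site-wise scan reconstructs ancestral states by Fitch parsimony on
the fixed species tree, resolving ambiguities deterministically toward
the parental state, and classifies every inferred substitution as
synonymous or nonsynonymous along minimal pathways. Each site's expected
nonsynonymous fraction comes from its observed codon composition (or a
uniform code-wide value), weighting transitions by a kappa estimated from
the inferred substitutions themselves — the counting analogue of running
the scan under a fitted nucleotide model. Significance uses the fact that
the synonymous rate does not depend on omega: the segment-wide mean
synonymous count per site estimates every site's substitution exposure,
and scaling it by the site's expected N:S odds gives the site's neutral
nonsynonymous mean, against which the observed count is tested one-sided
(Poisson). A site is flagged at alpha = 0.05 only if its N/S ratio also
exceeds the segment-wide ratio. We initially implemented the more obvious
conditional test (binomial on the site's own N among its N+S), but
conditioning on the site's substitution total throws away the rate
signal: strongly selected sites carry several-fold more substitutions,
and across a wide divergence range the conditional test's power at
omega = 4 plateaus near 10-20%, which is useless for the regimes this
package targets. The rate-based form reaches ~70% power under the same
conditions while keeping the type-I error at or below nominal (the
Poisson tail at small means is conservative). Two numerical guards: the
N:S odds are capped for sites with essentially no synonymous opportunity
(tryptophan columns), and all-gap columns are skipped and reported.

The segment-level test compares the total nonsynonymous count to its
Monte-Carlo null (independent Poisson draws per site, >= 2000 seeded
resamples) at the Bonferroni-corrected level 3.33e-3. Robustness re-runs
repeat the scan over the expected-fraction model grid and seeds; a site
is *robust* only if flagged under every setting, mirroring the practice
of retaining only sites stable across model choices. A column mask is
available to exclude lineage-specific insertions before scanning, and
masked/unmasked results can be compared side by side.

**Calibration conditions.** The packaged calibration
(`siteTestCalibration()`) runs 20 neutral and 20 power replicates on a
12-taxon balanced tree with 300 codons and kappa 4. The branch length,
0.15 substitutions/nt, was chosen by a divergence sweep during method
design: shorter branches starve the counts, longer ones saturate
parsimony; 0.15 sits where counting is still accurate but selected sites
(omega = 4 against an omega = 0.2 background) accrue enough substitutions
to be detected. This mirrors how comparative studies choose species at an
appropriate divergence for selection analyses. Under these conditions the
per-site type-I error is ~0.01-0.02 against a nominal 0.05, power at
omega = 4 sites is ~65-75%, background false flags are at or near zero,
and the neutral gene-level test essentially never reaches the Bonferroni
level.

# Cleavage sites and strain variants

`scanCleavageSites()` lifts the three aspartate self-cleavage positions
(CARD-p20, p20-linker, linker-p10 boundaries) from reference residue
coordinates through the alignment and reports, per species, the aligned
residue and any alternate aspartate within +/- 5 residues (configurable;
"nearby" has no published number), skipping gap columns so offsets count
residues of the scanned species.

Missense variants are classified by a three-way conservation rule applied
in fixed order: alternate residue observed in another species =>
*unlikely* to disrupt function; otherwise invariant column =>
*potential impact*; otherwise *unknown*. Strict invariance is the
default; a near-invariance option (e.g. 90%) exists but is off. Strain
recommendations count both *potential impact* and *unknown* variants
toward avoidance — untested variants are not evidence of safety — which
is also the convention that reproduces the published avoid list; strains
whose variants are all *unlikely* get *caution*, and strains with no
variants in the queried genes are *clean*.

# Worked example

```{r example, eval = FALSE}
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
res$events
```

# Problem sizes used by the shipped tests

The default layout reproduces a ~350 kb locus; the test and calibration
suites use compact layouts (3 kb intergenic spacers, 0.8 kb introns,
~45 kb loci) with 6-10 species, which exercise every code path at a
fraction of the cost, and the calibration conditions stated above. The
acceptance script regenerates all simulated datasets from scratch at
these sizes.

# Known limitations

* The annotation stage has no spliced aligner; splice-signal modeling is
  limited, and exon indices are matched across paralogs by position.
* Block detection cannot see similarity below ~70% identity despite the
  50% reporting floor (exact-seed limit).
* Parsimony-based substitution counting undercounts at high divergence;
  the dN/dS values reported by the scan are counting estimates and are
  expected to differ numerically from likelihood-based estimates on the
  same data (segment rankings, not values, are comparable).
* The site test assumes a homogeneous synonymous rate across sites within
  a segment; strong synonymous rate variation would make it
  anticonservative.
* The conversion caller needs conversion to be recent or recurrent
  relative to speciations; one-off ancient conversions are invisible to
  the distance rule by construction.
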