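---
title: "Methods: gene-centric integration of variants, conservation, phylogeny, copy number and structure"
author: "VariantScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-centric variant integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

VariantScape assembles, for one protein-coding gene, the views a molecular
study typically combines: variant records harmonized across public
databases and genome builds, per-residue evolutionary conservation from a
mammalian protein alignment, a distance-based phylogeny of the orthologs,
copy-number and survival summaries from tumor cohorts, structural interface
annotation, and hairpin-forming sequence features. The shipped
configuration describes TREX1, the three-prime repair exonuclease whose b
isoform (314 aa, single exon, chromosome 3p21.31) is the canonical frame,
but the gene model is plain-text configuration, not code, so the pipeline
applies to any single-exon gene with N-terminally nested isoforms.

# Variant harmonization

Sources export variants in different dialects and on different genome
builds. `readVariantTable()` normalizes each export through a plain-text
column map (`inst/extdata/dialects/`); `mergeGenomic()` merges records on
GRCh38 `(chrom, pos, ref, alt)` keys. Two normalization choices matter:

* **Minimal allele representation.** Shared prefix/suffix padding is
  trimmed before keying (a `CA>CG` at 100 equals `A>G` at 101). We do not
  left-align against a reference genome: no genome sequence is an input of
  this pipeline, and for the padding differences actually seen across the
  emulated dialects, prefix/suffix trimming is sufficient.
* **hg19 handling.** Rows from hg19-only sources first try an exact match
  against the recorded hg19 coordinates of already-merged records (sources
  that publish both builds provide these); the remainder are lifted through
  a block-based chain map. Positions covered by no block are returned as
  explicit misses and land in the removed-rows report; nothing is silently
  dropped, and every stage preserves `|input| = |kept| + |removed|`.

rsID discordance (one variant, several rsIDs; one rsID, several loci) is
reported machine-readably rather than blocking the merge — the manual
curation step it replaces cannot be automated faithfully. Allele conflicts
at one position are kept as separate records and flagged.

Protein-level grouping (`groupByProtein()`) parses HGVS-p-like strings
(one- and three-letter, frameshift and stop spellings), converts positions
into the b-isoform frame (isoform a adds 55 N-terminal residues; isoform c
lacks b's first 10), and checks each missense/synonymous variant against
the codon interval implied by the CDS; inconsistent rows are flagged, not
dropped, and unparseable strings are quarantined to a report.

The population-frequency class uses a strict threshold: frequencies
strictly above 0.0011 are `Elevated`, anything at or below it `Low`. The
threshold is the suggested pathogenic-variant cutoff for this gene; the
boundary itself is read as "does not exceed", hence `Low`.

# Conservation metrics

`columnMetrics()` computes five per-column summaries of a protein
alignment, designed to be fully reproducible rather than delegated to an
interactive viewer:

* **consensus** — the modal non-gap residue (alphabetical on ties, with a
  tie flag);
* **consensus support** — the percentage of *all* sequences carrying the
  consensus. The denominator includes gapped sequences; this convention is
  what makes reported support values integral multiples of 1/n.
* **occupancy** — the number of non-gap residues;
* **quality** — the mean BLOSUM62 score over unordered residue pairs,
  min-max rescaled to [0, 1] across the alignment. Any monotone
  BLOSUM-based summary would do; this one is deterministic and simple.
* **conservation** — 0–11. A column scores 11 only when it is one
  identical residue with no gaps. Otherwise the score counts (0–10) the
  physicochemical property classes (Taylor/Livingstone–Barton:
  hydrophobic, polar, small, tiny, aliphatic, aromatic, positive,
  negative, charged, proline) that are either present in every sequence or
  absent from every sequence. A gap carries no properties, so a gapped
  column can only conserve by absence; an all-gap column scores 0.

One consequence worth stating: with the all-sequence support denominator,
duplicating a non-consensus sequence *lowers* support (QQE at 66.7%
becomes QQEE at 50%), while the conservation score — a function of the
residue set and gap presence only — is unchanged under duplication. The
property tests assert exactly that.

`buildPositionMap()` gives the bijection between alignment columns and
ungapped reference positions (the k-th non-gap reference residue maps to
its column); `speciesMatches()` lists the other sequences carrying a
variant's alternate residue at that column, the cross-species evidence
used when judging whether a human variant is an evolutionarily tolerated
state.

# Phylogenetic distances and trees

Protein distances use pairwise deletion (each pair of sequences drops only
the sites where either has a gap) and the gamma-corrected Poisson
transform

$$ d = a\left[(1 - p)^{-1/a} - 1\right], $$

with shape $a = 1$ by default (giving $d = p/(1-p)$) and the plain Poisson
correction $-\log(1 - p)$ as the $a \to \infty$ limit. Saturated pairs
($p \ge 1 - 10^{-9}$) are set to a configurable cap (default 10
substitutions/site) and flagged; `njTree()` refuses capped matrices unless
told otherwise, since NJ on capped entries is not meaningful.

`njTree()` is the Saitou–Nei algorithm with the Studier–Keppler Q
criterion. Two numerical conventions are fixed for determinism: joins are
tie-broken by the smallest `(i, j)` index pair in the current matrix
order, and negative branch-length estimates (which NJ can produce on
non-additive matrices) are clamped to zero with the clamped deficit
recorded on the tree. On additive matrices the true tree and its branch
lengths are recovered exactly; the tests verify this and cross-check the
topology against an independent NJ implementation (`ape::nj`).

Bootstrap supports resample columns with replacement, re-infer NJ per
replicate, and label each internal edge with the percentage of replicates
containing its bipartition; replicates that produce a saturated distance
are dropped and counted. Trees are emitted unrooted; `rerootOutgroup()`
reroots on a designated outgroup.

# The synthetic-data generators

Every pipeline stage has a generator that produces inputs with known
ground truth, standing in for the downloaded datasets a real run would
use. All randomness flows from R's Mersenne–Twister via a single
`set.seed(seed)` per generated dataset, so outputs are byte-identical
across platforms for a given seed.

* `genAlignment()` builds columns by declared type (conserved residue,
  property-class draw, uniform random) with a per-cell gap rate. Truth is
  what is knowable by construction: conserved columns are exactly
  conservation 11 / support 100, per-column occupancy equals the
  generator's own gap count, and property-class columns carry a lower
  bound on the score.
* `genTreeSequences()` evolves gap-free sequences along a known tree under
  the 20-state equal-rates model — the generative counterpart of the
  Poisson distance correction. Over a branch of length $t$ a site differs
  from its ancestor with probability
  $\tfrac{19}{20}(1 - e^{-\frac{20}{19}t})$, uniformly over the other 19
  residues; this closed form is itself a test oracle. The simulator has no
  indels and no site-rate heterogeneity — gamma rates exist only in the
  distance correction — so passing recovery tests speak to topology
  estimation under the matched model, not to robustness under model
  misspecification.
* `genVariantSources()` plants unique coding SNVs with codon-consistent
  protein labels, scatters them over sources (some emitted on hg19 through
  the inverse chain map), and plants an exact number of rsID conflicts.
  Truth records the unique count, the protein partition and the conflicts.
* `genCnaSurvival()` draws GISTIC levels (losses split 9:1
  shallow:deep, gains 9:1 gain:amplification), arm status with a planted
  conditional co-occurrence probability, and exponential survival with a
  planted hazard ratio under independent exponential censoring.
* `genToyStructure()` builds CA-only chains and computes truth contacts by
  an exhaustive all-pairs distance check with the same radii table the
  module uses.

What the generators do *not* emulate: realistic mutational signatures,
indel evolution, linkage between variants, non-proportional hazards, and
full-atom side chains. Tests passing on synthetic data therefore validate
the algorithms' correctness against their stated models, not their
behavior on the full messiness of production database exports.

# Copy number, co-occurrence and survival

Discrete copy-number levels follow the GISTIC convention (−2 deep
deletion … +2 amplification); "loss" means level < 0 and "gain" level > 0.
Survival stratification uses two groups only — `loss` versus `wild_type`,
with copy gains counted as wild type — mirroring the two-strata design the
analysis emulates. Kaplan–Meier estimation and the log-rank test are
delegated to the survival package (deaths precede censorings at tied
times, the standard convention; the analysis is silent on ties), with a
brute-force O−E/V oracle in the tests. p-values are reported raw; with 32
histologies a multiple-testing correction would be defensible, and the
summary tables make applying `p.adjust` trivial, but the default mirrors
the uncorrected per-histology design. Co-occurrence fractions are
conditional: of the samples with the gene-level event, the fraction also
carrying the arm-level event; samples lacking arm status are excluded and
tallied.

# Structural interfaces

`findContacts()` declares two atoms in contact when their van der Waals
overlap $r_i + r_j - d_{ij}$ is at least −0.4 Å — the documented default
of the Chimera contact tool this reproduces, with zero hydrogen-bond
allowance. Radii are a Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, H 1.20, default 1.70 Å) shipped as data and overridable; hydrogens
are used when the structure contains them (crystallographic structures
typically do not, and the choice is simply "the atoms present"). A residue
pair is an interface pair when any atom pair qualifies. Structure residue
numbering is reconciled to isoform positions by a configurable offset
(zero when author numbering already equals b-isoform positions); variant
positions outside the modeled range are flagged `unmodeled` rather than
silently classified.

# Palindromes and base pairing

`findInvertedRepeats()` enumerates maximal inverted repeats (stem length,
loop length, mismatch budget; N never pairs; GU wobble only in RNA mode).
A stem always ends on a complementary pair — trailing mismatches belong to
the loop, not the stem. `maxBasePairs()` is the Nussinov base-pair
maximization DP with hairpin loops of at least 3 unpaired bases, returning
one deterministic optimal structure (the traceback prefers leaving the
left index unpaired, then the smallest partner). These are deliberate
combinatorial stand-ins for thermodynamic folding: the claim they support
is "complementary stems exist and can form hairpins", not a free-energy
prediction.

# Problem sizes and test design

The test-suite and acceptance-script problem sizes were chosen as the
smallest that make each statistical check sharp: 6-taxon trees with 5000
sites for topology recovery (binomial error on p-distances ≈ 0.007),
2000-sample cohorts for co-occurrence (99% CI half-width ≈ 0.019 at 0.88),
2000 null replicates of 500 per arm for the log-rank type-I error
(standard error ≈ 0.5%), 100 random toy structures for the contact oracle,
and exhaustive enumeration up to n = 12 for pairings. Determinism is
tested by re-running generators under fixed seeds.

Two published-data checks ship red by design of the artifact's inputs: the
per-position conservation targets need the deposited 159-sequence
placental alignment, and the stability-score correlation needs the
deposited 20-variant score table; neither file is redistributable inside
the package. The tests state precisely which file would enable them
(`inst/extdata/placental_trex1b.aln`, `inst/extdata/model_scores.tsv`) and
run the full computation when it is present.

# Known limitations

* The gene model assumes a single-exon CDS on the + strand with
  N-terminally nested isoforms; multi-exon genes would need an
  exon-aware codon map.
* Indel normalization is minimal-representation only (see above).
* NJ is the only tree method; likelihood-based inference is out of scope
  and better served by dedicated software.
* Arm-status calls are consumed as given; partial-arm events are whatever
  the upstream caller labeled them.
* The AMAS-style conservation convention fixes gap handling (conserve by
  absence only); viewers may differ on gapped columns, which is why the
  per-position checks report residue multisets on disagreement.
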