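---
title: "Phylogenetic footprinting of rDNA repeat units: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic footprinting of rDNA repeat units: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnafoot)
```

## The problem

Ribosomal RNA genes occur as hundreds of tandemly repeated units, each an
rRNA coding region followed by a ~30 kb intergenic spacer (IGS). The IGS is
excluded from chromosomal assemblies and is hard to manipulate genetically,
so its functional elements are poorly mapped. Phylogenetic footprinting
sidesteps the experimental obstacles: functional elements evolve more
slowly than their neutral surroundings, so aligning orthologous repeat
units from related species and looking for slowly evolving blocks yields a
candidate map of functional elements. `rdnafoot` implements that analysis
end to end — reconstructing repeat units from assembly contigs, projecting
a multi-species alignment onto a reference unit, scoring conservation with
a two-state phylogenetic hidden Markov model, mapping called regions onto
outgroup units, and overlaying the calls with functional-genomics tracks —
together with a synthetic-data generator that provides ground truth for
every stage.

## Repeat-unit reconstruction from assembly contigs

Because the units within a genome are nearly identical, a whole-genome
assembler collapses them into one consensus contig set whose read coverage
exceeds single-copy regions by roughly the repeat copy number (hundreds in
primates). `select_repeat_contigs()` exploits both signals: a contig is
kept when its mean coverage is at least `min_cov_ratio` (default 5) times
the **median** contig coverage and it aligns locally to a seed unit (a
known unit from a related species) at ≥ 80% identity over ≥ 200 bp. The
thresholds are package choices — the coverage principle is standard, but no
canonical cutoff exists; the median is used because repeat contigs are a
small minority of an assembly, so the median tracks the single-copy mode.

`orient_and_merge()` then orients each selected contig against the seed
(either strand), anchors it at its implied seed offset, and chains
consecutive contigs across exact or near-exact suffix/prefix overlaps
(default ≥ 30 bp, ≤ 2% mismatch). Tandem units are circular, so a
reconstruction is accepted up to circular rotation; the fragment tiling may
cross the unit origin at one point, and the merger therefore tries each
cyclic rotation of the offset-sorted chain until one merges. The result is
rotation-normalized so that position 0 coincides with the seed's position 0
whenever the merge covers the seed origin. Two in-silico validations
mirror the classical wet-lab checks: `in_silico_digest()` (a homing enzyme
that cuts once per unit linearizes a circular unit into a single fragment
of the full unit length, the basis of unit sizing) and `in_silico_pcr()`
(exact-match primer sites; the product is reported as the inclusive span
from the first base of the forward site to the last base of the
reverse-complement site). On the inclusive-span convention, the classic
human 18S probe primer pair spans 595 bases at its published coordinates
although the product is usually quoted as 594 bp; the package reports the
inclusive span and leaves the off-by-one to the caller's interpretation.

## Reference projection and similarity

A multiple alignment is projected onto its reference row by deleting every
column in which the reference carries a gap (`project_to_reference()`),
leaving columns in one-to-one correspondence with reference positions;
bidirectional coordinate maps are retained so alignment-space and
reference-space annotations can be interconverted. All internal coordinates
are 0-based half-open (the BED convention); conversions happen only at I/O
boundaries (GFF3) and in region labels, which are reported 1-based for
readability.

`sliding_similarity()` summarizes conservation per position: the mean,
over a 50 bp window centered at the position (1 bp step), of the fraction
of row pairs with identical non-gap bases in each column. Pairs involving
`-` or `N` count as non-identical but stay in the denominator, so
indel-rich segments score low — the desired behavior when satellite
insertions in one species should register as unconserved. The alternative
(dropping gap pairs from the denominator) is a documented variant the
similarity statistic could use; the published tool this mirrors does not
specify its rule, so the stricter convention was chosen and fixed. Window
values at the track edges come from truncated windows rather than `NA`, so
the track length always equals the reference length.

## The conservation model

Conservation calling is a two-state phylogenetic HMM in the phastCons
family. Each alignment column is an observation; its emission density
under either state is the phylogenetic likelihood of the column given a
tree `T` with branch lengths `t_b`, a reversible (REV) rate matrix `Q`
normalized to one expected substitution per site, and stationary
frequencies `π`, computed by Felsenstein pruning with transition matrices
`P(t) = exp(Qt)`:

* **nonconserved state** — branch lengths `t_b` as given;
* **conserved state** — branch lengths `ρ·t_b`, with `ρ ∈ (0, 1]`
  (default 0.3), or an independently supplied conserved model (e.g. the
  conserved half of a phastCons `.mod` pair).

Gaps and `N` are treated as missing data (all-ones partial likelihoods), so
a column missing in every non-reference row contributes `π`-only emissions
under both states: it is uninformative and extends flanking segments
rather than breaking them.

Transitions follow the phastCons parameterization: the conserved state is
left with probability `μ = 1/L_c` and entered with probability
`ν = μ·γ/(1−γ)`, where `L_c` is the prior expected conserved-segment
length (default 45 bp) and `γ` the prior conserved fraction (default 0.3)
— the published phastCons defaults, exposed in `segmentation_config()`
because the source analyses rarely print them. Posteriors come from scaled
forward–backward; segment boundaries from the Viterbi path by default
(ties broken toward nonconserved), with a posterior-threshold mode
(`≥ 0.5`) as the alternative. Viterbi was chosen because it yields clean
non-overlapping segments without a threshold parameter. Candidate segments
shorter than `min_region_bp` (default 10) are dropped; survivors are
labelled `c-1`, `c-2`, ... by ascending start and carry their mean
posterior as score.

### Numerical choices

`P(t)` is computed by eigendecomposition of the symmetrized generator
`D^{1/2} Q D^{-1/2}` (`D = diag(π)`), which is exact for reversible `Q`
and lets one decomposition serve every branch and both states; a
scaling-and-squaring fallback covers ill-conditioned cases. Pruning is
vectorized across columns (one 4×4 matrix per branch applied to 4×L
partial-likelihood matrices) with per-node rescaling, and forward–backward
uses per-column scaling, so likelihoods stay finite for arbitrarily long
alignments. The pruning implementation is verified against exhaustive
ancestral-state enumeration to 1e-10, and the forward likelihood against
exhaustive path enumeration to 1e-9, in the test suite.

### A note on ρ and detectability

Detection rests on the likelihood **ratio** between the two emission
models. When `ρ ≈ 1` the states coincide and nothing is called; as `ρ`
decreases from 1 toward the rate at which an element actually evolved,
discrimination grows. Pushing `ρ` far **below** the element's true rate
makes the conserved model fit the element poorly and calls shrink again —
called coverage is *not* monotone in `ρ`, and the test suite encodes
exactly this: no calls near `ρ = 1`, growing coverage as `ρ` leaves 1, and
truth-scale coverage at the generative `ρ`.

## Outgroup mapping and sequence identities

`map_regions_to_outgroup()` aligns each called region's reference
subsequence to an outgroup unit by affine-gap local alignment (both
strands) and declares it mapped when identity is **strictly** greater than
the threshold (default 0.5, the ">50% identity" rule; a best hit at
exactly the threshold does not map). Identity counts identical columns
over **all** alignment columns, gaps included in the denominator — the
conservative convention, fixed and documented because published identity
tables rarely state theirs. Scoring defaults are BLAST-like (+2/−3, gap
−5 open, −2 extend) and configurable. `global_identity()` applies the same
machinery globally, with optional exclusion intervals (e.g. microsatellite
tracts whose copy number varies between unit assemblies) whose columns are
dropped from both numerator and denominator; exclusion intervals must be
supplied explicitly by the caller. Alignment itself is delegated to
`Biostrings::pairwiseAlignment()`; an independent dynamic-programming
oracle in the test suite pins the exact scoring convention (a gap of
length k costs |open| + k·|extend|).

## Feature overlay and zones

`intersect_regions()` annotates called regions against typed feature
tracks (transcripts with FPKM, CAGE peaks, chromatin-state intervals,
small-RNA coverage, known elements) strand-agnostically by default, since
conservation is strandless. Two published rules are implemented exactly:
small-RNA regions are maximal runs of per-base coverage ≥ 5 (the boundary
value qualifies), and transcripts are displayed as expressed when
FPKM > 1, with FPKM exactly 1 assigned to the low class (the source
convention describes only `> 1` and `< 1`; the boundary assignment is this
package's documented choice).

A *zone* — a stretch of the spacer where conserved regions co-occur with
transcription evidence — is defined operationally here, because the
concept is used descriptively in the literature without a stated rule: a
region carries evidence when it overlaps a transcript, CAGE peak, or
TSS/promoter/enhancer chromatin state in ≥ `min_cell_lines` (default 2)
distinct cell lines; evidence-bearing regions are single-linkage
clustered with inter-region gaps ≤ `max_gap_bp` (default 1500), and
clusters of ≥ `min_members` (default 3) become zones. These three
parameters are calibration knobs recorded in the run manifest, and zone
boundaries should be read as descriptive annotations, not inferences.
`zone_accounting()` then splits regions into known (overlapping the
packaged known-element track, or any user-supplied one) and unknown, and
counts the unknown regions that zones absorb.

The packaged known-element annotation carries only records whose
coordinates follow from published positions (the promoter's upstream and
core control elements at −156..−107 and −45..+18 relative to the
transcription start, mapped onto a unit whose origin is the transcription
start, with the core element split across the origin; the coding/IGS
partition of the 43,972 bp human unit). Terminator (Sal-box) sites are
motif-defined — `find_sal_boxes()` scans for the 11 bp consensus
`GGGTCGACCAG` with a mismatch allowance — and the stress-induced IGS
transcripts must be supplied as user tracks, since their coordinates are
not reproduced here.

## The synthetic-data generator

`simulate_alignment()` evolves sites independently down a tree under the
REV model: the root is drawn from `π`, each branch applies `P(t_b)`
outside planted elements and `P(ρ·t_b)` inside them. The default scenario
is a desk-scale mirror of a primate IGS analysis: a 7-taxon
human-to-marmoset tree with near-neutral spacer-like branch lengths
(total tree length 0.5 substitutions/site, human–marmoset distance ≈ 0.3,
i.e. ~25% observed divergence), a 5 kb sequence, five planted elements of
100–300 bp at `ρ = 0.3`, and a GC-rich background (0.2/0.3/0.3/0.2) with
transition bias, reflecting spacer base composition. Simulation is
substitution-only by default, so the leaf matrix is itself the alignment;
tests that exercise projection insert reference gaps explicitly.

What the generator deliberately does **not** emulate: indel processes and
alignment error (real spacer alignments contain long satellite-driven gap
runs; here gap handling is exercised synthetically rather than emerging
from an indel model), microsatellite and transposable-element turnover,
rate variation within the nonconserved background, GC-biased gene
conversion, and concerted evolution among repeat copies. Passing the
recovery tests therefore demonstrates that the segmentation machinery is
correct and well calibrated under its own model assumptions — not that
real alignments satisfy those assumptions.

`simulate_repeat_contigs()` reproduces the coverage signature of a
collapsed tandem repeat (repeat fragments at copy-number × base coverage
with 5% log-normal noise, circular permutation, random strands, 300 bp
overlaps) plus single-copy background contigs.
`simulate_feature_tracks()` places transcript/CAGE/chromatin intervals
over planted elements with probability `enrich_prob_in` (default 0.9) and
over 500 bp background tiles with `enrich_prob_out` (default 0.05), per
cell line, with log-normal FPKM (meanlog 0.5, sdlog 1). All generators
are pure functions of their parameters and seed.

## Problem sizes and runtime

The shipped tests and the acceptance script use the default 5 kb × 7-taxon
scenario (one segmentation ≈ 0.4 s), 50-seed recovery suites, alignment
oracles on ≤ 60 bp pairs, and enumeration oracles on ≤ 4-taxon trees and
≤ 12-column chains — sizes chosen so the whole battery runs in a few
minutes on one CPU while keeping every estimate's Monte-Carlo error small
relative to its acceptance margin. The same machinery runs unchanged on a
full 44 kb unit × 6-species alignment (the pruning pass is linear in
columns; a 44 kb segmentation takes a few seconds).

## Known limitations

* Model parameters (`ρ`, transition probabilities) are fixed, not
  EM-estimated; reproducing a published region count exactly may require
  calibrating `target_coverage`/`expected_cons_len` against the published
  region table, and the run manifest records whatever values were used.
* Emissions are column-independent given the state; indels are missing
  data, not evidence.
* `in_silico_pcr()` requires exact primer matches; degenerate or
  mismatched binding is out of scope.
* Contig merging assumes near-exact overlaps (≤ 2% mismatch) as produced
  by consensus assemblers; it is not a general-purpose assembler.
* Zone calling is descriptive; no enrichment statistics are attached.
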