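---
title: "Synthetic communities and the genome-resolved MAG workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic communities and the genome-resolved MAG workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`synmag` implements a genome-resolved metagenomics workflow — compositional
binning of assembled scaffolds into metagenome-assembled genomes (MAGs),
marker-based bin quality control and decontamination, exact-match read
recruitment with normalized relative abundance, consensus-based metabolic
pathway calling with domain-level gene-family statistics, and concatenated
ribosomal-protein phylogenetics — together with a ground-truthed synthetic
community generator that exercises every stage end to end. Real sediment
metagenomes are large, unlabeled, and depend on external annotation
services; the synthetic community provides the labels that turn each stage
into a testable claim.

This vignette explains the models, the tunable parameters and why their
defaults are what they are, what the generator does and does not emulate,
and the numerical choices that matter.

# The synthetic community generator

## Genomes

Each genome is sampled from an order-3 Markov chain over A/C/G/T. Order 3
is the natural choice because the downstream compositional signature is the
tetranucleotide frequency (TNF) profile: an order-3 chain controls exactly
the distribution of 4-mers. Per genome, every one of the 64 context rows of
the transition table is drawn from a Dirichlet distribution (concentration
2 per base), which gives genuinely distinct 4-mer structure across genomes.
The table is then exponentially tilted — the C and G columns are scaled by
a common factor and rows renormalized — and the tilt factor is solved by
bisection against the chain's stationary GC (computed by power iteration on
the 64-state context chain), so the realized GC lands within ~0.002 of the
target for megabase-scale genomes.

The five default genomes span GC 0.32–0.68. The span is deliberately wide:
the contaminant-injection policy (`gc_extreme`) requires a donor at least
30 GC points away, so the extreme pair (0.32, 0.68) is the one channel
through which GC-deviant contaminants flow, and the three interior genomes
receive none. Default genome length is 3.2 Mb, which yields roughly
170–200 scaffolds of at least 5 kb per genome under the fragmentation law —
enough for the binning benchmark to be meaningful while the whole pipeline
still runs in well under a minute per stage.

A generation-time assertion computes genome-level TNF profiles and requires
every pair to be at least 0.02 apart (Euclidean, 136-dimensional canonical
profiles). This floor is a well-posedness guarantee, not a tuning knob: if
a configuration produced compositionally indistinguishable genomes, a
binning benchmark against it would be meaningless, so generation fails
loudly instead. Under the defaults the realized minimum separation is
~0.065, three times the floor.

## Scaffolds, contaminants, reads

Scaffold lengths are log-normal (median 9 kb, sdlog 0.9) truncated to
200 bp–177,401 bp, mimicking a short-read assembly's length range, with a
deliberate sub-5 kb tail (~25% of scaffolds) so the binning length gate has
something real to exclude. Scaffolds tile each genome without gaps or
overlaps; lengths sum exactly to genome length, and the truth table records
half-open 0-based coordinates.

Contamination relabels 10% of each eligible bin's scaffolds as coming from
the GC-most-distant donor (when that donor is at least 30 points away),
recording the true origin. This creates exactly the cases the
decontamination rules must catch: scaffolds whose GC and per-gene taxonomy
deviate from their host bin.

Reads are paired 2×125 bp with insert size uniform in 360–420 bp, mates on
opposite strands, and a per-base substitution rate of 0.002 (a realistic
short-read error magnitude). Genome read share is proportional to depth
weight × genome length; the default weights 3/1.5/1/0.75/0.5 make the
community unevenly abundant, as real communities are. The generator does
not emulate indels, chimeric reads, quality-score decay along the read, or
strain-level variation — so passing tests say nothing about robustness to
those; they validate the exact-match and compositional semantics of the
pipeline stages.

## Markers, annotations, evidence

Marker placement is exact by construction: `round(completeness × M)`
distinct markers present, `round(duplication × M)` of them doubled. The
defaults per genome (completeness 100%, 93%, 80%, 60%, 40%; duplication 0,
0, 13.3%, 6.7%, 0) are chosen to straddle both quality gates, so the gate
test exercises keep and reject decisions in the same run.

Annotation records simulate two databases with per-database detection
probability 0.95 for truly present enzymes and a 2% per-database false
positive rate. True records get e-values at or below 1e-20 by construction —
a real hit is one that passes the homology gate; false positives draw
from a wider e-value range and are partially removed by the gate. Detection at 0.95 per database puts single-key pathway sensitivity
near 0.90 (both databases must fire for key confirmation), which is the
realistic regime for well-annotated marker enzymes.

All randomness flows from one top-level seed through named substreams
(`genome_1`, `fragment_3`, `reads`, ...), so any stage can be regenerated
independently and the whole pipeline is byte-reproducible.

# Compositional binning

## TNF profiles

Profiles count all overlapping 4-mers; windows containing a non-ACGT
symbol are skipped, and counts are normalized by the number of valid
windows. By default a tetramer is pooled with its reverse complement
(16 palindromes + 120 merged pairs = 136 classes) because assembly strand
is arbitrary; the raw 256-dimensional profile is available by flag.
Scaffolds below 5 kb are excluded from binning. Longer scaffolds are cut
into non-overlapping 10 kb windows (a trailing window shorter than 5 kb is
merged into its predecessor), which stabilizes the placement of very long
scaffolds and gives each scaffold multiple votes.

## SOM training

The self-organizing map is toroidal, sized to about `⌈√(5n)⌉` nodes in a
~1:1.6 rectangle. Online training runs 20 epochs with learning rate
decaying linearly 0.25 → 0.01 and the Gaussian neighborhood radius
decaying linearly from half the larger grid dimension to **0.3**. The
final radius matters: if it stays at 1, neighboring prototypes never
decouple, each genome collapses onto a single node, and the U-matrix is
flat — there are no ridges to threshold. Ending below 1 lets the
prototypes inside a cluster spread over its internal variance while
interpolating nodes remain stranded on the ridges between clusters.

Two reproducibility choices: training is deterministic for a fixed seed,
and the profile set is canonicalized (lexicographically sorted) before the
seeded presentation order is drawn, so shuffling the input rows changes
nothing — permutation invariance holds exactly, not approximately. The
mean quantization error is recorded after every epoch; the decaying
schedule makes it decrease overall (the final checkpoint is below the
first), though online SOM does not guarantee strict per-epoch monotonicity.

## Bin delineation

The U-matrix (mean weight-space distance of each node to its grid
neighbors) is thresholded and connected components of interior nodes
become bins. Two design points:

* **Threshold.** The default is an Otsu two-class split of the node
  U-values rather than a fixed percentile. A fixed percentile presumes a
  fixed fraction of the grid is cluster interior, but that fraction varies
  with how densely the data occupy the map; at some scales a 60th-percentile
  threshold empirically merges well-separated genomes. A percentile remains
  available as a parameter.
* **Occupancy.** Interior nodes must also be the best-matching unit of at
  least one profile. This is the density condition of U*-matrix practice:
  unoccupied low-distance nodes are interpolation corridors between
  clusters, and without the condition they connect separate genomes into
  one component. With it, bin recovery on the default community is exact
  (adjusted Rand index 1.0) at every scale we tested.

Profiles mapping to boundary nodes stay "unbinned"; scaffolds take the
majority bin over their windows, ties resolving to the lowest bin id with
"unbinned" losing ties. Best-matching-unit ties resolve to the lowest bin
id and then the lowest node index, so assignments are deterministic.

Coverage is not a binning feature by default — the profiles are purely
compositional — but a per-scaffold coverage column can be appended by the
caller as an extra standardized feature, and labeled reference profiles can
be mixed into training; both are purely additive.

# Bin quality control

Completeness is the percentage of a single-copy marker list present at
least once in a bin; duplication the percentage present twice or more. The
estimator is a deliberate simplification: one configurable marker list
(default the 15 ribosomal proteins), no lineage-specific marker-set
selection. The gates are strict above 50% completeness (a bin at exactly
50.0 is rejected) and inclusive at 10% duplication (exactly 10.0 is kept).

Decontamination is **one-pass with frozen means**: the bin's mean GC, mean
gene confidence, and majority taxonomy are computed on the initial
membership, and every scaffold's verdict uses those same values — removing
one scaffold can never change another's verdict within the pass. A second
pass is a separate, explicit call; the workflow deliberately does not
iterate, mirroring a single curation step. The three removal rules: GC
deviating more than 0.25 (absolute, fraction scale) from the bin mean;
majority gene taxonomy at the configured rank differing from the bin
majority (ties in either majority break toward retention); mean gene
confidence deviating more than 25 percentage points. The GC rule is
interpreted as absolute percentage points: a relative reading (25% of the
mean) would remove scaffolds at |ΔGC| ≈ 0.12 for a 0.5-GC bin, far too
aggressive for real genomes. "Confidence" is the per-gene annotation
confidence score (0–100). Bins with fewer than three scaffolds pass
through unfiltered with a warning (deviation from a mean of fewer than
three items is ill-posed), and scaffolds without evidence are retained and
flagged rather than silently judged.

# Read recruitment and abundance

A read is recruited to a MAG iff its complete sequence occurs exactly
(zero mismatches, full length) as a substring of a member scaffold on
either strand. Matching is implemented with a pre-built dictionary scan
(Biostrings `PDict`) over both strands, and the test suite pins it to a
naive substring scan — the two must agree read for read. Both mates count
independently; a read matching several scaffolds of one MAG counts once; a
read matching several MAGs counts once per MAG and is reported as
ambiguous. Reads with non-ACGT symbols can never match (tallied as
unmatchable); reads whose length differs from the configured 125 bp are
rejected with a count, because a full-length criterion is length-specific.

Abundance is `(reads / genome_size) / sample_total × 1e6` — reads
normalized by genome size, corrected for sample sequencing depth, scaled
by a million. The printed values are only comparable within this
normalization; rankings are invariant to the exact reading of the scale.
Note one subtlety the synthetic truth exposes: reads drawn across a
scaffold fragmentation boundary (~1.4% at 9 kb median scaffold length)
cannot full-length-match any single scaffold, so the observed recruitment
rate on fragmented references sits slightly below the error-only
expectation `(1-e)^125 ≈ 0.779`.

# Functional profiling

E-value-scored records pass at e ≤ 1e-20 (inclusive); bit-score records
pass per-enzyme custom thresholds (default floor 50). An enzyme is
*confirmed* for a MAG when at least two distinct databases report it
("multiple databases" read as its minimal consistent value, ≥ 2,
configurable); single-database enzymes stay *unconfirmed*. A pathway is
called present iff every key enzyme is confirmed AND strictly more than
50% of its components are detected — where the component fraction counts
confirmed *and* unconfirmed enzymes, but keys require confirmation. The
asymmetry is intentional: keys are the diagnostic evidence and carry the
multi-database requirement; the component fraction measures pathway
coverage. The call is monotone: adding a detected component or a
confirming database can never flip present to absent.

Pathway definitions ship as editable structured text
(`inst/extdata/pathways.txt`): a starter set of five anaerobic sediment
processes (reverse methanogenesis / mcrA, dissimilatory sulfate reduction
/ dsrAB, beta-oxidation with its four steps as keys, denitrification /
napA, fumarate-addition hydrocarbon activation / bssA+assA). The set is
illustrative and user-editable, not a curated catalog.

Gene-family contrasts use a two-sided Mann-Whitney U test per family on
per-MAG counts between archaea and bacteria, Bonferroni-corrected over the
families tested. The implementation enumerates the full permutation null
(valid under ties) whenever the smaller group has at most 8 observations
and the enumeration stays below 2×10^5 splits, and otherwise uses the
normal approximation with tie correction and continuity correction; the
two-sided p is `min(1, 2·min(P(U ≤ u), P(U ≥ u)))`, with constant data
giving p = 1 by convention. Family means are normalized by the number of
MAGs in each domain (every MAG in the denominator), not genome size. The
workflow's domain contrast runs on a simulated 34-archaea / 77-bacteria
panel — a realistic recovery scale; a five-genome community cannot power a
rank test (the minimum two-sided exact p at group sizes 2 vs 3 is 0.2).

# Marker phylogeny

Two catalogs: the 15 syntenic ribosomal proteins (rpL2, 3, 4, 5, 6, 14,
15, 18, 22, 24; rpS3, 8, 10, 17, 19) and an extended single-copy set (the
enumerated ribosomal proteins plus IF-2, the two phenylalanyl-tRNA
synthetase subunits, tRNA pseudouridine synthase B, porphobilinogen
deaminase, and ribonuclease HII) carried as a second catalog through the
same code path. Extraction keeps the longest sequence per (taxon, marker)
and logs duplicates. Per-gene alignment is delegated — synthetic tests
supply already-aligned blocks, and an external aligner can be used on real
data; no alignment algorithm is implemented here.

Concatenation follows catalog order, gap-fills missing blocks, records
1-based inclusive block coordinates, and enforces the inclusion rule at
**≥ 8 markers** exactly: a taxon with 8 is in, with 7 is out. The rule is
applied to both catalogs. Distances are p-distances with pairwise deletion
(per-pair shared columns; complete deletion would waste most of a partial
MAG's signal), with an optional Poisson correction `-ln(1-p)`; pairs
sharing fewer than 50 columns are flagged unreliable, and a pair sharing
none is an error naming the pair.

Tree inference is neighbor joining, written in-repo: deterministic
tie-breaks (smallest Q, then lexicographically smallest pair), negative
branch lengths clamped to zero with the deficit moved to the sister branch
(their sum is preserved), exact on additive matrices — the test suite
checks topology and path-length recovery against generated trees and
cross-checks topologies against an independent implementation. Maximum
likelihood is deliberately out of scope; the emitted supermatrix FASTA and
partition table are exactly what an external ML tool consumes. Bootstrap
support resamples supermatrix columns with replacement, rebuilds the NJ
tree, and reports the fraction of replicates containing each original
split; it is deterministic for a fixed seed.

# Problem sizes and numerical choices

The default study configuration is five 3.2 Mb genomes (~900 binnable
scaffolds, ~1,600 window profiles on a ~7×13 map), 20,000 read pairs with
2,000 recruited in the workflow stage, 100 bootstrap replicates, and
15×60-residue marker blocks — sizes chosen so each stage completes in
seconds while every statistic retains enough resolution to be meaningful.
Profile sums are asserted to 1e-9; BMU and Q-matrix ties use 1e-12
comparisons; the GC calibration bisects to 1e-4. Degenerate inputs are
handled explicitly rather than silently: empty TNF profiles are flagged
(not returned as zeros), bins under three scaffolds skip decontamination
with a warning, constant data gives p = 1, and a supermatrix pair with no
shared columns raises an error.

# Known limitations

* The generator's genomes are stationary Markov chains: no repeats, mobile
  elements, rRNA operons, or within-genome compositional heterogeneity, so
  binning results here are an upper bound on real-data performance.
* The completeness estimator uses one flat marker list, not
  lineage-specific sets; its absolute values are only as good as the list.
* Exact full-length recruitment is deliberately strict; real pipelines
  tolerate mismatches, so absolute recruitment rates are not comparable
  across tools.
* The starter pathway catalog is a five-process illustration; real
  analyses should supply their own definitions file.
* NJ on p-distances is a distance method; deep or rate-heterogeneous
  divergences belong to an external ML tool fed with the emitted
  supermatrix.
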