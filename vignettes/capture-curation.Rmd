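---
title: "Curating target-capture loci and measuring gene-tree conflict with capcure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating target-capture loci and measuring gene-tree conflict with capcure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capcure)
```

# The problem

Target capture (hybrid enrichment) sequences a predefined set of exon
loci across many taxa by hybridizing library fragments to tiled RNA
baits. Before the loci can be concatenated into a supermatrix or used
for gene-tree inference, the raw data must be curated: PCR-duplicate
read pairs removed, reads and contigs sorted into per-locus bins,
paralogous contigs excluded, introns spliced out, cross-contaminated
samples detected, and uninformative loci set aside. After inference,
conflict among gene trees around each branch of the species tree needs
to be quantified. `capcure` implements this chain as small, testable
operations plus a simulator that plants each artifact with a truth
table, so that every screen can be validated end-to-end on data whose
ground truth is known.

# The model and its assumptions

## Bait tiling

Baits of length $b$ (default 120 nt) are tiled with overlap $v$
(default 60 nt), i.e. step $s = b - v$. The exon is right-padded with
`N` to the smallest length $L \ge \max(\ell, b)$ with $L - b$ divisible
by $s$, giving exactly $1 + \lceil \max(0, \ell - b)/s \rceil$ baits
and two-fold coverage away from the ends. Padding is an interpretation:
vendors "pad sequence lengths" without documenting the rule, and
right-padding with uppercase `N` is the choice that makes the tiling
arithmetic exact while never triggering the soft-mask filter. A bait is
discarded if it contains *any* lowercase (soft-masked) character; an
optional maximum-`N` filter (off by default) can additionally drop
baits dominated by padding.

## Read-pair deduplication

Two pairs are replicates when the first 20 bp of mate 1 *and* the first
20 bp of mate 2 agree (case-insensitively). Scanning in input order,
the first member of each prefix class is kept — the natural convention
when the original procedure does not specify which copy survives. Pairs
with a mate shorter than the prefix are never removed. The operation is
idempotent and order-stable by construction.

## Locus binning and orthology

The original pipeline BLASTs reads and contigs against the bait set.
`capcure` replaces the external dependency with a self-contained
seeded matcher: exact $k$-mers ($k = 11$) are indexed over the baits,
seed hits are grouped by diagonal on both strands, and each seeded
diagonal is scored by its best ungapped segment (match $+1$, mismatch
$-1$; a Kadane scan, so an exact substring of length $n$ scores $n$).
A sequence joins the bin of the locus with the single highest score at
or above `min_score` (default 50); ties resolve to the
lexicographically smallest locus id with a warning. At the divergences
the simulator produces (up to ~15% from the reference) the expected
per-position score is strongly positive, so assignments remain exact
while unrelated loci score near zero.

Reading frames are predicted by translating all six strand/offset
combinations under the standard genetic code and choosing the frame
with fewest internal stops. Ties prefer a frame that ends in a clean
terminal stop, then the longest stop-free stretch, then the fixed
order `+0,+1,+2,-0,-1,-2`. The terminal-stop preference is
deliberate: with a short 5' overhang the biologically correct
`ATG...stop` frame can have a *shorter* stop-free stretch than an
overhang-shifted frame that happens to avoid stops, and only the
terminal stop distinguishes them. Terminal stops are trimmed; if
internal stops remain the translation is truncated at the first one
with a warning.

Intron splicing chains collinear diagonal segments between a contig
and its locus reference (strictly increasing in both coordinate
systems, maximizing total score) and concatenates the covered contig
segments in reference order. Chance matches can extend a segment a few
bases past an exon junction, so consecutive chain segments may overlap
by a bounded amount (up to 50 nt); the overlap is charged against the
chain score and trimmed from the downstream segment, which keeps each
reference position used exactly once. A handful of sites flanking a
junction can still be lost when substitutions sit at the boundary —
the spliced product is a high-identity subsequence of the true exon,
not a base-perfect reconstruction.

The reciprocal-best-hit screen re-searches each binned contig against
the *full* bait set and flags it as a potential paralog when the top
locus disagrees with its bin. The original study reciprocally BLASTed
against the reference genome used for bait design; lacking that
genome, the bait set is the stand-in target space. This surrogate has
a structural blind spot: when bins are themselves recomputed with the
same scorer, a contig can never disagree with its own bin. The screen
therefore shows its value on bins produced elsewhere (the pipeline
accepts precomputed bins, and the simulator emits the capture-truth
bins a noisier binning would have produced) — matching the original
design, where binning and the reciprocal check used different target
spaces.

## Cross-contamination

For each pair of taxa from *different* presumed-related groups, and
each locus containing both, the p-distance is computed over columns
where both rows hold an unambiguous `A/C/G/T`. The locus is flagged
for the pair when the distance is at or below 0.002 — at 500
comparable sites, at most one mismatch. The per-pair percentage of
flagged loci among evaluable loci is the decision statistic: genuinely
conserved loci can produce near-zero distances between distant taxa,
but not across a large fraction of loci, so only a pair whose
percentage reaches `pct_alarm` (default 5%; an artifact choice — the
original study simply concluded that an observed maximum of 1.44% meant
no contamination) is reported as suspect. The screen is advisory: it
reports, it does not drop samples. Intra-group pairs are skipped by
default since close relatives legitimately have tiny distances. The
denominator counts only loci where both taxa are present and
evaluable; whether the original script divided by all loci is unknown,
and both-present is the interpretation that keeps the statistic a
proper fraction.

## Treelikeness and locus selection

Phylogenetic informativeness is scored per locus by quartet mapping on
p-distances: for each four-taxon subset $\{a,b,c,d\}$ the three sums
$d_{ab}+d_{cd}$, $d_{ac}+d_{bd}$, $d_{ad}+d_{bc}$ are compared. Under
an additive tree metric the smallest sum sits uniquely below the other
two, which are *equal* (the four-point condition). A quartet counts as
resolved when the winning gap $s_2 - s_1$ exceeds `resolution_margin`
(default 0) **and** is not exceeded by the additivity violation
$s_3 - s_2$. The second clause matters: p-distances on finite
alignments are essentially never exactly tied, so a min-only rule
degenerates to scoring ~1 on pure noise, whereas for noise the three
sums are mere order statistics and the gap comparison fails about half
the time — this is what separates signal from randomized columns.
Treelikeness is the resolved fraction; quartets touching an undefined
distance are skipped. All $\binom{n}{4}$ quartets are enumerated when
they fit under `max_quartets` (default 2000), otherwise a seeded
uniform sample is used and the seed is logged. This distance-based
score is an explicit surrogate for the matrix-reduction software used
in the original pipeline, which is a black box; the selection composite
`treelikeness x (taxon coverage fraction)` mirrors that tool's
trade-off between signal and matrix occupancy. Ranking ties break by
taxon count, then locus id, so selection is deterministic. Loci with
fewer than four effective taxa (rows with at least one determined,
non-gap character) cannot define an unrooted topology and are excluded
up front.

## Supermatrix and statistics

Concatenation takes the taxon universe as the union over loci and
fills absentees with gap blocks; partitions are recorded 1-based
inclusive and exported in the RAxML one-line format. The fill
character is `-` rather than `N` — standard supermatrix practice, and
immaterial to the gap/undetermined proportion, which counts both. For
statistics, characters are uppercased and `?`, `.` and all ambiguity
codes unify with `N`; a site pattern is the full column string over
the fixed taxon order and the distinct-pattern count is plain column
uniqueness (an ML program's printed pattern count may additionally
drop fully undetermined columns; that variant is not replicated). The
supermatrix export format is relaxed PHYLIP plus the partition file —
the combination any downstream ML tool accepts.

## Internode certainty

For each internal branch $b$ of the reference tree, gene trees are
restricted to their shared leaves; a tree is *evaluable* for $b$ when
the restricted split still has two or more leaves on both sides. With
$f(b)$ the fraction of evaluable trees containing the restricted split
and $f(b_1)$ the frequency of its most frequent conflictor (four-point
set-intersection test), the internode certainty is

$$IC = \sigma \left(1 + p \log_2 p + p_1 \log_2 p_1\right),
\qquad p = \frac{f(b)}{f(b)+f(b_1)},\; p_1 = 1 - p,$$

with $\sigma = -1$ iff $f(b_1) > f(b)$ — the negative sign marks a
branch where the gene trees prefer an alternative resolution. With no
observed conflictor, $IC = 1$ if the split is ever supported, else 0.
ICA generalizes to the set $C$ of conflictors with frequency at least
5% of the top frequency (a configurable artifact choice; no canonical
threshold exists): $ICA = \sigma(1 + \sum_{c \in C} q_c \log_{|C|}
q_c)$ with $q$ normalized over $C$. Tree certainty TC is the sum of IC
over internal branches and relative TC divides by the branch count.
Conflictor identities are keyed on each gene tree's own leaf universe;
with complete gene trees this is exactly the textbook computation (and
is verified against a naive recount oracle), while across partial
trees with different leaf sets the same topological conflictor can
split into several keys — a known limitation of this variant, which
does not affect $f(b)$ itself. A validated neighbor-joining front-end
(`nj_tree`) turns simulated distance matrices into surrogate gene
trees for testing.

# The simulator: what it emulates and what it does not

`simulate_dataset()` generates a pure-birth species tree scaled to
unit height, splits the taxa into two groups at the root (the
"presumed closely related" table), and evolves each locus — an intact
open reading frame — by a uniform-replacement (Jukes-Cantor-like)
substitution process with a per-locus rate drawn from
`subs_rate_range` (default 0.05-0.15 expected substitutions per site
per unit path). Mutations that would create in-frame stop codons are
reverted, a crude purifying selection that keeps frame-prediction
truth well defined. Planted artifacts, each recorded in a truth table:

* **Duplicate read pairs** — a fraction (default 20%, a typical PCR
  duplicate rate) of pairs are copied, with tails beyond the compared
  prefix occasionally altered; accidental prefix collisions among
  non-planted pairs are re-drawn so the clean-data null is exact.
* **Paralogs** — a duplicate locus M diverged ~3x the mean ortholog
  rate from locus L joins the bait set; the paralog contig is near M
  but *claimed* for L, emulating a noisier upstream binning.
* **Cross-contamination** — a donor's aligned sequence overwrites the
  recipient's at a deterministic `round(fraction * n_loci)` of loci,
  plus per-site residual noise (at most 0.001, below the screen
  threshold).
* **Introns** — a `GT...AG`-flanked random insert at a codon boundary
  in a configurable fraction of contigs; contigs are written on a
  random strand.
* **Missing taxa** — per-locus dropout (default 10%), floored at four
  taxa so every locus remains scoreable.

Defaults (20 taxa, 100 loci of 300-900 nt) are a desk-scale stand-in
for a real capture experiment an order of magnitude larger. The
simulator does **not** model sequencing error, indels inside exons,
capture-efficiency biases, or rate heterogeneity across sites — so a
green test establishes that each screen recovers its planted artifact
under clean separation (ortholog divergence well under the paralog
divergence, contamination distances well under background divergence),
not that the thresholds are optimal on noisy real data.

# Numerical choices and degenerate inputs

* Sequence characters: `U` normalizes to `T`; `?` and `.` to `N`;
  IUPAC ambiguity codes are preserved on IO but treated as
  undetermined by every statistic; `-` stays distinct from `N` except
  in the combined gap/undetermined proportion.
* p-distances with fewer than `min_overlap` comparable sites (default
  1) are undefined and propagate as skipped loci or skipped quartets,
  never as zeros.
* All tie-breaks (binning, selection ranking, frame order, NJ) are
  deterministic and documented; quartet subsampling is seeded.
* Degenerate trees: fewer than four leaves yield an empty bipartition
  set; star trees have no internal branches and a TC of 0 over 0
  branches is reported as `NA` relative TC.
* `deduplicate_pairs` compares raw post-trim text; quality values are
  parsed and ignored (trimming is upstream).

# Known limitations

* The reciprocal-best-hit surrogate cannot flag paralogs in bins it
  computed itself (see above); it requires independently produced bins
  to be informative, exactly as in the original two-target-space
  design.
* Spliced exons can lose a few boundary sites at substitution-dense
  junctions.
* ICA conflictor aggregation across partial gene trees fragments by
  leaf universe.
* The tiling rule assumes fixed-step "flexible" tiling; adaptive
  vendor-side tiling densities are not reproduced.

# A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_taxa = 10, n_loci = 12, paralog_count = 2,
                  rng_seed = 137)
sim <- simulate_dataset(cfg, out_dir = "sim")
manifest <- run_pipeline(list(
  inputs = list(
    reads_r1 = "sim/reads_1.fastq", reads_r2 = "sim/reads_2.fastq",
    contigs = "sim/contigs.fasta", baits = "sim/baits.fasta",
    bins = "sim/truth/claimed_bins.tsv",
    loci_dir = "sim/loci", groups = "sim/groups.tsv"),
  out_dir = "run"))
str(manifest$stages)
```

The manifest counts (pairs kept/removed, contigs flagged, loci
selected, supermatrix statistics) equal the simulator's truth tables;
the test suite asserts this for clean and fully artifact-laden
configurations, and `scripts/acceptance.R` reports the locus
accounting computed the same way.
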