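---
title: "Methods: combinatorial CAR libraries, scCAR-seq demultiplexing and pooled-screen statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial CAR libraries, scCAR-seq demultiplexing and pooled-screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

carforge models the computational side of a pooled CAR T-cell engineering
screen: a combinatorially shuffled signaling-domain library is designed and
validated in silico, each sequenced cell is linked to its CAR variant from
long-read amplicons, and the pooled single-cell screen is analysed for
CAR-induced transcriptional phenotypes. This vignette explains the models
and procedures, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical conventions.

## The library design model

A second-generation CAR places co-stimulatory domains (CD28, 4-1BB)
membrane-proximal to CD3&zeta;, whose three immunoreceptor tyrosine-based
activation motifs (ITAMs) trigger downstream signaling. The shuffled design
replaces the co-stimulatory domain and the first CD3&zeta; ITAM segment
with one domain from each of two pools:

* **Pool A** — intracellular segments of co-stimulatory or co-receptor
  proteins, carrying no ITAM.
* **Pool B** — segments that each carry exactly one ITAM (including the
  first segment of CD3&zeta; itself, which reconstitutes the full
  intracellular domain when chosen).
* A truncated CD3&zeta; segment with the remaining **two** ITAMs is
  retained in the chassis.

Every assembled variant therefore carries exactly 0 + 1 + 2 = 3 ITAMs, a
design that conserves total activating capacity while shuffling signaling
context. `assemble_variant()` enforces this invariant by rescanning the
translated ORF; `enumerate_library()` builds the full |A| x |B| matrix of
variants (15 x 12 = 180 in the default configuration).

### ITAM scanning

The motif is modelled as `Yxx[L/I] - x{s} - Yxx[L/I]` with the spacer `s`
between 6 and 12 residues (configurable). `itam_scan()` scans left to
right, taking the shortest completing spacer at each match and resuming
after the matched motif, so counts are left-greedy and non-overlapping.
The scanner is implemented as an explicit position loop; the test suite
checks it against an independent regular-expression enumeration on random
sequences.

### Type IIS digestion and ligation

Ordered (Golden Gate) assembly relies on a Type IIS enzyme cutting outside
its recognition site. The default enzyme is AarI with the standard
`CACCTGC(4/8)` geometry, i.e. 4-nt 5' overhangs; `enzyme_def()` accepts
any other geometry. `typeIIs_digest()` finds sites on both strands,
partitions the top strand at the cut positions and records each junction's
overhang; `ligate_fragments()` chains fragments by overhang
complementarity and refuses ambiguous or mismatched junctions. The chassis
cassette carries two outward-facing sites whose excision exposes three
distinct, mutually non-complementary junction overhangs (upstream|A,
A-linker, B|downstream), which is what makes the one-pot assembly ordered.
The round-trip property — digesting a re-amplified variant recovers both
domain inserts byte-exactly — is checked for the whole library.

Coordinates are 0-based half-open internally; FASTA output and reports use
1-based inclusive conventions. The "minimal linker" joining domain A to
domain B contributes its codons to the ORF (6 nt, Gly-Ser, by default).

## Synthetic fixtures

The study's actual domain and chassis nucleotide sequences are not public,
so `make_fixture_pools()` generates stand-ins that satisfy every structural
constraint: in-frame, stop-free, ITAM content by pool (0/1/2), no stray
recognition sites in any segment, template or A-linker-B junction, and
deterministic under a seed. Backgrounds are sampled from a tyrosine-free
amino-acid alphabet and reverse-translated with random synonymous codons,
so planted ITAMs are the only motifs present. These fixtures preserve the
combinatorial structure of a real library but not any particular sequence
content, codon usage or amplicon length distribution; nothing downstream
depends on those.

### Read simulation

`simulate_sccar_reads()` emits one read per barcoded CAR cDNA molecule:
adapter, 16-nt cell barcode, 12-nt UMI (10X Chromium v3 lengths), the
constant upstream tail, `domainA + linker + domainB`, and a downstream
anchor taken from the Strep-tag-proximal constant region. Reads are
emitted in either orientation (50/50) with configurable per-base
substitution/insertion/deletion rates; a configurable fraction of cells
carries two distinct variants (multi-CAR cells, e.g. double integrations).

Molecules per cell follow a negative binomial (mean 10, dispersion 0.5,
truncated at one molecule). The depth reflects the assay's regime:
scCAR-seq amplifies every barcoded CAR molecule already present in the 10X
cDNA pool, so each cell is represented by tens of molecules, and a
two-CAR cell reveals both constructs with near certainty. At much lower
depth the strict multi-CAR discard rule would structurally under-count
multiplets (a one-read cell can never show two constructs) — a property of
the assay, not of the demultiplexer. The real per-cell molecule
distribution is unpublished; the default is declared, not inferred.

The expression simulator `simulate_expression()` draws each cell's cluster
from its variant's propensity row and its counts from a negative binomial
(baseline mean 2, dispersion 0.5, log-normal gene effects and cell depth),
with 25 planted marker genes per cluster at 4-fold up-shift and a per-cell
mitochondrial fraction drawn from 1-10%. The default design plants 8
clusters of which 5 are CAR-induced: benchmark positive controls put 90%
of their mass there, negative controls 4.5%, and the 20 library variants
span CIC propensities from 0.05 to 0.95 — the graded ground truth used to
benchmark enrichment ranking. What these simulations do **not** emulate:
doublet transcriptomes, ambient RNA, batch/donor structure, realistic
long-read error profiles, or continuous (non-discrete) cell states. A
pipeline passing on them demonstrates correctness of the statistics, not
robustness to every artefact of real data.

## scCAR-seq demultiplexing

`call_reads()` processes each read in four stages:

1. **Orientation** — the downstream anchor is searched on the forward
   strand, then on the reverse complement; reads without an anchor are
   `no_anchor`.
2. **Barcode/UMI** — the adapter is located (20% mismatch tolerance, with
   indels as a fallback), the 16-nt window after it is corrected against
   the whitelist by the unique-neighbour rule at Hamming distance
   `max_mismatch` (default 1, the droplet-sequencing convention), and the
   12-nt UMI follows.
3. **Variable region** — extracted between the constant upstream tail and
   the anchor; an exact hash against all known `A + linker + B` inserts
   short-circuits error-free reads.
4. **Domain calls** — each pool's references are pre-screened by shared
   11-mer counts and the two best candidates aligned (global in the
   reference, local in the region; match 2, mismatch -3, gap open 6,
   extend 3). A call needs identity at least `min_identity` (default
   0.85); if the two best identities differ by less than `tie_margin`
   (default 0.02) the read is `ambiguous_domain`.

`demux_cells()` collapses UMIs per (barcode, variant), drops variants
below `min_umis_per_variant` (default 1 — the strict behaviour), and
labels each cell `single`, `multi` (two or more constructs observed:
discarded, since a mixed transcriptome cannot be attributed) or
`unassigned`. An optional dominance ratio can rescue near-single cells;
it is off by default. `library_completeness()` summarises plasmid-level
calls as an A x B count matrix with completeness (observed/possible
combinations) and evenness (Shannon entropy of observed counts normalised
by `log(n_observed)`, defined as 0 for a single observed combination).

## Pooled-screen statistics

* **QC** (`qc_filter()`): keep cells with `500 < detected genes < 10000`
  and mitochondrial percentage `< 15` — all strict inequalities, so cells
  sitting exactly on a threshold are removed.
* **Normalization** (`lognormalize()`): `ln(1 + 1e4 * x / total)` per
  cell; zeros stay zero.
* **Subsampling** (`subsample_cells()`): at most 250 cells per variant and
  500 per negative control group, without replacement, seeded. This keeps
  clonally expanded variants from dominating the clustering.
* **Clustering** (`cluster_cells()`): top 2,000 genes by standardized
  dispersion (variance/mean, z-scored within 20 gene-mean bins), z-scaling
  clipped at +/-10, optional least-squares regression of nuisance
  covariates (e.g. cell-cycle scores), PCA to 30 components, an unweighted
  Euclidean 20-nearest-neighbour graph, and Louvain modularity
  optimisation (resolution 1 by default) under an explicit seed. No
  community standard fixes k, the PC count or the resolution; these
  defaults recover the planted fixtures and are knobs, not claims.
* **Stability** (`stability()`): repeat subsample+cluster and score every
  pair of rounds by the adjusted Rand index on the shared cells. The ARI
  uses the standard pair-counting form
  `(sum_ij C(n_ij,2) - E) / (M - E)`; the degenerate case where both
  partitions are trivial returns 1.
* **CIC detection** (`detect_cics()`): cluster `c` is CAR-induced iff
  `mean_pos f[,c] >= min_ratio * mean_neg f[,c]` and
  `mean_neg f[,c] <= max_neg_fraction` (defaults 2.0 and 0.05). "Strong"
  enrichment and depletion are qualitative notions; the thresholds are
  this package's declared operationalization, both configurable. A zero negative mean with positive presence counts as
  infinitely enriched; a cluster empty in both groups is not a CIC.
  `cic_enrichment()` then sums each variant's fractions over CICs — the
  screen's activity measure. Variants need `min_cells = 50` cells to be
  reported (lowered to e.g. 20 for CD8-restricted analyses); the cell
  count doubles as the reporting confidence score.
* **Pseudo-bulk and PCA** (`pseudobulk()`, `pca_embed()`): per-group mean
  of normalized expression; centered PCA with non-increasing variance
  fractions.
* **Gene-set scores** (`geneset_score()`): per cell, genes are ranked by
  decreasing expression (average ranks on ties), ranks capped at
  `r_max + 1` (default 1500); the signature's Mann-Whitney statistic
  `U' = sum(rank) - n(n+1)/2` gives the score `1 - U'/(n * r_max)`,
  clipped to [0, 1]. With the stated cap the exact-zero extreme is
  attained by single-gene signatures; multi-gene signatures entirely
  beyond the cap score `(n-1)/(2 r_max)` before clipping, which the cap
  convention leaves as is. Per-variant means and fold changes against a
  named benchmark CAR are provided by `geneset_summary()`.
* **Differential expression** (`rank_sum_de()`): two-sided Mann-Whitney U
  per gene with normal approximation and tie correction (no continuity
  correction), Benjamini-Hochberg adjustment across tested genes, and
  pre-filters on detection fraction and absolute log fold change. The
  implementation is vectorised; tests pin it to `stats::wilcox.test` and
  verify null calibration at nominal alpha.

## Numerical and design notes

* Every stochastic operation takes an explicit seed and runs under a
  local RNG scope, leaving the caller's random stream untouched.
* Problem sizes in the test suite: the full 180-variant library; 2,000
  cells for demultiplexing scenarios; 3,000 cells x 1,000 genes x 8
  clusters for planted-structure recovery; 2,000 null genes at 100 vs 100
  cells for DE calibration. These recover the planted truth with margin
  (clustering ARI ~1, exact CIC recovery, Spearman ~0.99).
* Multi-donor integration (reciprocal PCA, SCTransform, Harmony) is out
  of scope; all screen statistics accept any externally supplied
  partition, so enrichment on an integrated labelling is computable by
  passing that partition directly.
* Known limitations: the demultiplexer assumes the read layout produced
  by the documented amplicon scheme (it tolerates errors and orientation
  flips, not arbitrary fusion reads); `cluster_cells()` materialises a
  dense cell-cell distance matrix, which is the simple and exact choice
  up to ~10^4 cells but not beyond; evenness compares only observed
  combinations, so a library with one dominant and one rare member still
  scores high completeness but its imbalance shows in the evenness value.
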