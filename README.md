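# carforge

Design, demultiplex and analyse pooled chimeric antigen receptor (CAR)
signaling-domain screens.

CAR T-cell engineering has explored only a small corner of the natural
immune signaling repertoire. One way to widen it is combinatorial: shuffle
intracellular signaling segments from two pools — pool A (co-stimulatory
segments, no ITAM) and pool B (single-ITAM segments) — into a CAR chassis
that retains a truncated two-ITAM CD3&zeta; segment, so that every variant
conserves exactly three immunoreceptor tyrosine-based activation motifs
(ITAMs). The resulting library (15 × 12 = 180 variants in the reference
design) is integrated into primary T cells, stimulated by tumour
co-culture and read out by single-cell RNA-seq, with a parallel long-read
amplicon assay (scCAR-seq) linking each cell barcode to its CAR variant.
Variant activity is then scored by enrichment in **CAR-induced clusters**
(CICs): transcriptional clusters enriched in stimulated benchmark CARs
(f<sub>pos</sub> ≥ r · f<sub>neg</sub>) and depleted in negative controls
(f<sub>neg</sub> ≤ 0.05).

carforge implements this pipeline end to end, for users who want to design
such libraries, validate assembly in silico, demultiplex scCAR-seq reads,
or analyse a pooled screen:

* **Library design** — Type IIS (Golden Gate) digestion/ligation
  simulation with configurable enzyme geometry (`enzyme_def`,
  `typeIIs_digest`, `ligate_fragments`), ITAM scanning
  (`Yxx[L/I]x{6,12}Yxx[L/I]`, left-greedy), variant assembly and full
  enumeration with three-ITAM validation.
* **scCAR-seq demultiplexing** — orientation-aware read calling with
  whitelist barcode correction, alignment-based domain identification,
  UMI collapse, strict single/multi/unassigned cell assignment, and
  library diversity reports (completeness, evenness).
* **Screen analysis** — QC (500 < genes < 10000, MT% < 15, strict),
  log-normalization (scale 10⁴), capped subsampling (250 per variant /
  500 per control), kNN-Louvain clustering with adjusted-Rand-index
  stability, CIC detection, per-variant CIC enrichment, pseudo-bulk, PCA,
  rank-based gene-set scoring (UCell-style U statistic) and Wilcoxon
  rank-sum differential expression with BH correction.
* **Synthetic data** — seeded generators for domain pools, barcoded long
  reads with errors and multi-CAR cells, and negative-binomial count
  matrices with planted clusters and control groups, so everything is
  testable without external data.

## Worked example

```r
library(carforge)

# 1. design: 15 pool-A x 12 pool-B fixture domains on a shared chassis
fx  <- make_fixture_pools(nA = 15, nB = 12, seed = 7)
lib <- enumerate_library(fx$poolA, fx$poolB, fx$chassis)
length(lib)
#> [1] 180
head(variant_manifest(lib), 3)
#>   label domain_a domain_b orf_length itam_count
#> 1 A1-B1       A1       B1        570          3
#> 2 A1-B2       A1       B2        579          3
#> 3 A1-B3       A1       B3        558          3

# 2. demultiplex simulated scCAR-seq reads (2% substitutions, 4% multi-CAR)
cfg   <- read_sim_config(n_cells = 500, whitelist_size = 1000, seed = 11)
sim   <- simulate_sccar_reads(lib, fx$chassis, cfg)
calls <- call_reads(sim$reads, fx$poolA, fx$poolB, fx$chassis,
                    whitelist = sim$whitelist)
dx    <- demux_cells(calls)
round(dx$summary, 4)
#>     single_rate      multi_rate unassigned_rate
#>          0.9599          0.0401          0.0000

# 3. pooled screen on a planted count matrix (3,000 cells, 8 clusters,
#    5 of them CAR-induced)
ecfg <- expr_sim_config(seed = 5)
esim <- simulate_expression(ecfg)
qc   <- qc_filter(esim$counts)
norm <- lognormalize(qc$counts)
part <- cluster_cells(norm, seed = 5)
em   <- detect_cics(cluster_fractions(qc$counts$meta, part))
em
#> enrichment_matrix: 24 variants x 8 clusters; CICs: 3, 4, 5, 6, 7
head(sort(cic_enrichment(em), decreasing = TRUE), 5)
#>       V20       V19   pos_BBz   pos_28z       V18
#> 0.9500000 0.9200000 0.8915663 0.8800000 0.8000000
```

The demultiplexer recovers the simulated truth (here 96% of cells singly
assigned, 4% discarded as multi-CAR — matching the planted 4% multiplet
rate), the clusterer finds the 8 planted clusters, `detect_cics` flags the
5 clusters enriched in the benchmark CARs and depleted in the controls,
and the CIC enrichment ranking follows the planted per-variant
propensities, with the benchmark 28z/BBz CARs scoring near the top.

A command-line interface wrapping the same functions ships as
`inst/cli/carforge` (subcommands `design`, `simulate`, `demux`,
`diversity`, `screen`), each run writing a JSON provenance record.

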