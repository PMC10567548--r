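# spatialcite

Read processing for spatial co-profiling of proteins and transcripts in
tissue. In this assay family, a tissue section stained with a cocktail of
antibody-derived DNA tags (ADTs) is barcoded in situ by two perpendicular
microfluidic flows — row barcodes A1..A50, then column barcodes B1..B50 —
so that every 25-µm pixel carries a unique spatial address code AiBj.
Paired-end sequencing then yields two libraries (RNA and ADT) in which
Read 1 holds the payload and Read 2 holds `UMI + barcode B + linker +
barcode A`.

`spatialcite` turns those FASTQ files into analysis-ready matrices:

- **demux** — parse Read 2, gate on the ligation linker, error-correct both
  spatial barcodes against whitelists (unique match within Hamming distance
  1; ties dropped), and assign every read a pixel `(row, col)`;
- **quantify** — match ADT tags to the antibody panel, assign transcript
  reads to genes (toy exact k-mer assigner, or an external aligner's
  read-to-gene table), collapse UMIs (distinct-UMI counting by default, the
  directional 1-mismatch network rule optionally), and build sparse
  features × pixels matrices;
- **qc / normalize / score** — per-pixel UMI and feature counts, centred
  log-ratio (CLR) normalization for protein
  (`y = ln(x+1) − mean_f ln(x+1)` within each pixel), library-size
  log-normalization for RNA, mean-z gene-signature scores (e.g. the Tph
  signature LAG3 / PDCD1 / CXCR6), and pseudo-bulk aggregation;
- **simulate** — a ground-truth tissue simulator (Poisson molecule counts
  per domain, random UMIs, PCR duplication, substitution errors) that writes
  both libraries plus a per-read provenance log, so the whole pipeline is
  testable with no external data.

Intended users: developers of spatial multi-omics workflows who need a
transparent, fully testable reference implementation of the demultiplexing
and counting stages, and anyone who wants to prototype downstream analysis
against simulated spatial CITE-seq-style data.

## Worked example

```r
library(spatialcite)

fx    <- make_fixtures("demo_fx", seed = 1)        # whitelists, panel, transcriptome, tissue
wlA   <- load_whitelist(fx$whitelist_a, "A")
wlB   <- load_whitelist(fx$whitelist_b, "B")
panel <- load_panel(fx$panel)
model <- read_tissue_model(fx$tissue)
model
#> Tissue model: 10x10 pixels, 3 domains (red_pulp, white_pulp, capsule)
#>   20 genes, 30 antibodies, ADT background rate 0.1

sim <- simulate_run(model, panel, fx$transcriptome, list(A = wlA, B = wlB),
                    err = error_model(substitution_rate = 0.005,
                                      pcr_duplication = 2, seed = 7),
                    out_dir = "demo_sim")
sim
#> Simulated run in demo_sim
#>   RNA: 4069 molecules -> 8257 read pairs
#>   ADT: 24084 molecules -> 47955 read pairs

cfg <- load_config()
cfg$paths <- list(whitelist_a = fx$whitelist_a, whitelist_b = fx$whitelist_b,
                  panel = fx$panel, transcriptome = fx$transcriptome)
res <- run_pipeline(cfg, sim$rna_r1, sim$rna_r2, sim$adt_r1, sim$adt_r2,
                    "demo_out")
res$protein
#> Spatial protein counts: 30 features x 100 pixels, 2733 nonzero, total 25786 UMIs
res$qc$protein
#> Pixel QC (protein): 100 pixels, mean UMI/pixel 257.9, mean features/pixel 27.3
str(res$stats$demux_adt)
#> List of 7
#>  $ total      : int 47955
#>  $ short_read : int 0
#>  $ fail_linker: int 26
#>  $ fail_bcA   : int 22
#>  $ fail_bcB   : int 34
#>  $ ambiguous  : int 0
#>  $ passed     : int 47873
```

Reading the numbers: 24,084 true ADT molecules were sequenced at ~2×
duplication into 47,955 read pairs; 47,873 (99.8%) pass the linker and
barcode gates at a 0.5% substitution rate, and distinct-UMI collapse brings
them back to 25,786 counted molecules — slightly above the true molecule
count because substitution errors inside the 10-nt UMI mint spurious
"new" molecules, exactly as in real data. The mean of 27.3 detected
proteins per pixel out of a 30-plex panel reflects the near-saturating
per-pixel detection this assay family reports.

`demo_out/` contains MatrixMarket matrices with `features.tsv` /
`pixels.tsv` sidecars, long-form `long.tsv` tables (row, col, feature,
count), per-pixel QC TSV + JSON summaries, CLR and log-normalized matrices,
and a `manifest.json` with the echoed configuration and its hash. Downstream
steps (CLR, scoring, pseudo-bulk):

```r
clr <- clr_normalize(res$protein)        # per-pixel zero-sum
sc  <- signature_score(lognorm_rna(res$rna), tph_signature("RNA"))
pb  <- pseudobulk(res$protein)           # totals + CLR of totals
```

A thin subcommand CLI over the same functions ships at
`inst/cli/spatialcite.R` (`fixtures`, `simulate`, `run`, `demux`).

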