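---
title: "Methods: from spatially barcoded reads to normalized pixel matrices"
author: "spatialcite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spatially barcoded reads to normalized pixel matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialcite)
```

## The assay and the computational problem

In deterministic in-tissue barcoding, two sets of DNA barcodes are delivered
over a fixed tissue section through perpendicular microfluidic channels: row
barcodes A1..A50 first (each carrying an oligo-dT capture region), then
column barcodes B1..B50, ligated in situ. Every 25-µm channel intersection —
a *pixel* — thereby acquires a unique spatial address code AiBj. When the
tissue has additionally been stained with a cocktail of antibody-derived DNA
tags (ADTs: an antibody conjugated to an oligo with a tag sequence unique to
that antibody, a UMI and a poly(A) tail), the same barcoding captures both
mRNAs and ADTs, and two sequencing libraries are prepared. In each library,
Read 1 carries the payload (a cDNA fragment, or the ADT tag) and Read 2
carries, in order: the UMI, spatial barcode B, a ligation linker, and
spatial barcode A.

The computational task this package solves is the inverse map: from raw
paired FASTQ files back to two feature-by-pixel count matrices (protein and
RNA), and onward to per-pixel QC, normalization and signature scores.

## Read-2 layout and its defaults

`read_layout()` records byte offsets and lengths for the UMI, barcode B,
linker and barcode A segments. The published protocol defers the exact oligo
sequences to supplementary tables, so the defaults here follow the
conventions of this assay family: 8-nt spatial barcodes, a 10-nt UMI, a
30-nt ligation linker, and 15-nt ADT tags. Every length and offset is
config-overridable (`load_config()`), so a run with different oligo designs
only needs a YAML file, not code changes. Segments must not overlap and must
fit inside the declared read length; the simulator additionally requires a
contiguous layout starting at offset 0, which is how these libraries are
actually constructed.

## Demultiplexing model

Each read pair passes a fixed gate sequence, and is counted exactly once, at
its first failure:

1. **structural**: Read 2 shorter than the layout span (`short_read`);
2. **linker**: Hamming distance to the expected linker `> max_hamming_linker`
   (default 2 over 30 nt — a loose gate whose job is to reject ligation
   artefacts, not sequencing errors);
3. **barcode A**, then **barcode B**: whitelist correction within
   `max_hamming_bc` (default 1 for 8-nt barcodes).

Correction returns the unique whitelist entry within the radius; exact
matches always win. If two entries tie at the minimal distance the read is
*ambiguous* and dropped — never arbitrarily resolved, because a wrong pixel
is spatial cross-contamination, the worst failure mode for this assay. The
radius is safe when `2 * max_hamming <` the whitelist's minimum pairwise
Hamming distance; `load_whitelist()` computes that distance at load time,
warns when the radius is unsafe, and demultiplexing then falls back to exact
matching for that axis. With the shipped whitelist generator (minimum
pairwise distance 3) the guarantee is: a read whose barcode carries at most
`max_hamming` substitutions is never assigned to a wrong pixel. Reads with
more substitutions than that in a single barcode are overwhelmingly
rejected; the residual chance that a double error lands within distance 1 of
a different whitelist entry is on the order of 10^-5 per read at a 0.5%
substitution rate, which is what the acceptance script's measured
mis-assignment fraction reflects.

The UMI used for deduplication is the Read-2 UMI carried by barcode B. ADTs
also carry their own internal UMI, but the counting convention of the
standard ADT tools this pipeline mirrors uses the barcode read's UMI, so
that is the default here (the collapse operates on whatever UMI the demux
records carry, so an internal-UMI variant only needs a different layout).

No quality-score filtering is applied by default: the upstream tools this
pipeline re-implements do not describe any, and the simulator writes
constant Phred-40 qualities.

## Feature assignment and UMI collapse

**ADT tags** are matched like barcodes: slice the tag region from Read 1,
find the unique panel tag within Hamming 1, drop ties.

**Transcripts** are assigned by an exact k-mer lookup (default k = 31)
against a toy transcriptome: the payload's k-mers are looked up and the read
is assigned iff they hit exactly one gene. This is deliberately not an
aligner — real runs should STAR-align Read 1 and feed the resulting
read-to-gene table in via `load_external_assignments()` /
`run_pipeline(rna_assignments =)`; the toy assigner exists so the synthetic
path is closed and testable offline.

**UMI collapse** defaults to `exact`: the count for a (pixel, feature) is
its number of distinct UMI sequences, matching the default behaviour of the
standard ADT counting tool. A `directional1mm` mode implements the standard
directional network rule (an edge from UMI *u* to UMI *v* when they differ
at one position and `count(u) >= 2*count(v) - 1`; network roots are counted,
absorbing transitively in decreasing-count order, ties broken
lexicographically for determinism). Because the simulator draws UMIs
uniformly at random, collisions are possible; all recovery tests therefore
compare against the simulator's distinct-(pixel, feature, UMI) truth, not
raw molecule counts.

## Matrices

`build_matrix()` emits a sparse features-by-pixels integer matrix with
pixels labelled `"{row}x{col}"` and ordered row-major. Protein matrices keep
every panel antibody as a row even when all-zero, so the panel size (e.g.
273-plex human, 189-plex mouse) stays structurally visible and per-pixel
protein counts are well defined; RNA matrices drop never-observed genes by
default. The pixel universe is every pixel with at least one passed read;
image-based tissue cropping is out of scope, but a pixel-label filter
(`keep_pixels`) accepts an externally derived tissue mask.

## Normalization and scoring

Protein counts are CLR-transformed: `y = ln(x + 1) - mean(ln(x + 1))`, mean
over all features within a pixel (`margin = "per_pixel"`, the default). The
per-pixel margin is the compositional reading of ADT data — each pixel's
tag counts compete for the same capture and sequencing budget; the
alternative per-feature margin is exposed as a flag because popular
implementations have switched conventions between versions. The +1
pseudocount is required for zeros and matches common ADT practice. Under the
default margin every pixel's values sum to zero (tested to 1e-9), and a
pixel with counts (3, 0, 0) maps to (0.9242, -0.4621, -0.4621).

RNA counts get a plain library-size log-normalization
`ln(1 + scale * x / colsum)` with `scale = 10^4`; variance-stabilizing
transforms and clustering are downstream of this package's scope, and the
log-normalized matrix is what the signature score consumes.

**Signature scores** use `mean_z`: each signature feature is z-scored across
pixels (zero-variance features excluded), and a pixel's score is the mean of
the z-scores. The published description of the Tph (peripheral helper T
cell) score names its genes — LAG3, PD-1, CXCR6 — but no formula; mean-z is
the minimal defensible choice, invariant to gene order and duplicates, and
the gene list is an argument, not a constant. `tph_signature()` ships the
symbol mapping (PD-1 → gene PDCD1; protein-side anti-CD279).

**Pseudo-bulk** sums counts over pixels per feature after dropping pixels
with fewer than 10 total UMIs — mirroring the minimum-UMI cell filter used
when such spatial profiles are compared against single-cell ADT data — and
returns raw and CLR-transformed totals.

## The simulator: what it emulates and what it does not

`simulate_run()` draws molecule counts per (pixel, feature) as
Poisson(domain mean), the simplest generative model consistent with UMI
count data (a negative-binomial option is a natural extension). Each
molecule receives a uniform-random 10-nt UMI and `1 + Geometric` read-pair
duplicates with the configured mean, Read 2 is assembled from the pixel's
true barcodes, Read 1 is the ADT tag plus poly(A) or a fixed-length (90 nt)
random transcript substring, and uniform per-base substitutions are applied
to both reads. Every read is logged (read id, pixel, feature, UMI) in a
provenance table: the oracle for recovery tests. Output is byte-identical
for identical seeds.

Demo tissues (`make_demo_tissue()`) sketch lymphoid and skin geometries
(red/white pulp + capsule; extrafollicular/crypt/germinal-centre light and
dark zones; epidermis/dermis/vascular + a localized infiltrate), each
domain carrying a disjoint marker set at 10-fold enrichment over a base
level of 0.5 RNA and 2 ADT molecules per pixel per feature. The nonspecific
ADT background is a free parameter (no published noise model exists for it);
the default of 0.1 molecules per pixel per antibody makes isotype controls
visibly nonzero without dominating markers.

The simulator does **not** model barcode diffusion between channels, ADT–
mRNA reverse-transcription competition (beyond what the profile means
encode), indels (substitution-only, as in the upstream tools), variable
quality scores, or cell morphology within a pixel. Passing recovery tests
therefore demonstrates the correctness of the demultiplexing and counting
logic under a faithful read architecture — not performance on real tissue
noise.

## Problem sizes and numerical choices in the test suite

The small-scale configuration is a 10x10 grid, 20 genes and a 30-plex panel
(about 25k ADT and 4k RNA read pairs at the default means) — it runs the
full end-to-end identity check in seconds. The full-scale structural runs
use the 50x50 grid with cocktail-sized panels (273 human / 189 mouse) at
reduced per-pixel means (0.2 ADT, 0.02 RNA molecules per feature), since the
structural properties they verify — panel row counts and full 50-channel
coverage — do not depend on depth. The signature-recovery experiment uses a
10x20 grid split into two 100-pixel arms with the three Tph genes 10-fold
enriched in one arm, scored on log-normalized counts and compared with a
one-sided rank-sum test.

Degenerate inputs are handled explicitly: empty count matrices refuse CLR;
all-zero pixels log-normalize to zeros without division; constant signature
genes are excluded from the z-mean; an empty demultiplexed library yields
empty records with conserved (all-zero) stats.

## Known limitations

- The toy assigner requires exact 31-mers; at high substitution rates RNA
  assignment loses reads (protein assignment, with Hamming-1 tag matching,
  is more robust). This mirrors the division of labour in real runs, where
  alignment is external.
- Whitelist correction is substitution-only; barcode indels shift the whole
  layout and are not recovered.
- Pixel inclusion is read-driven; without an external tissue mask,
  off-tissue pixels with stray reads appear in the matrices.
- The per-pixel averages printed for the published tissue datasets derive
  from deposited sequencing data; the package recomputes such summaries via
  `qc_metrics()` on any matrix, but does not ship that data.
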