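---
title: "Methods: cross-modal integration of serial-section spatial omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal integration of serial-section spatial omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Serial FFPE sections of one tissue block can be profiled with three
complementary spatial technologies: submicron-resolution spatial
transcriptomics on a barcoded capture chip (0.5 µm spot pitch),
mass spectrometry imaging of metabolites, glycans and tryptic peptides
(20 µm pixels), and sequential multiplex immunofluorescence
(0.23 µm pixels, one channel per protein marker plus DAPI). Because each
modality sees a *different* physical section, integrating them requires a
common coordinate frame. `spatialfuse` implements that workflow end to end:
reads are demultiplexed to chip spots, spots are aggregated into bins,
binned expression is clustered (Leiden), each bin50-sized square becomes a
"Leiden voxel" carrying a globally unique 16-bit index, and the other
modalities are registered onto this indexed raster by landmark affine
transforms with nearest-neighbour label warping. Per-voxel records then
hold gene expression, mean ion intensity per m/z window, and phenotyped
cell counts, and a stack of registered sections can be resampled into an
isotropic 3D volume.

Because clinical specimens profiled this way are rarely shareable, the
package ships a first-class synthetic tissue phantom that generates all three raw
modalities from one ground-truth model, with known misalignments and
read-level noise, so every stage is testable against truth.

## Read processing model

Read 1 carries the spatial barcode (CID, bases 1–25) and the molecular
identifier (MID, bases 26–31); read 2 carries the transcript sequence.
Demultiplexing accepts an exact CID match, otherwise a *unique*
Hamming-distance-1 neighbour; an ambiguous correction rejects the read
rather than risking spatial misassignment. MIDs containing an N, or more
than two bases below Q10 (strictly `< 10`), are filtered. Gene assignment
is tag-based: read 2 is matched exactly against a toy reference in which
host and mitochondrial tags carry MAPQ 255, a multi-mapping decoy carries
MAPQ 0, and microbial tags map to a small fixed taxonomy (classes
Actinomycetia and Gammaproteobacteria). Hits at MAPQ ≤ 10 are discarded,
exercising the same filter a genome aligner's output would pass through;
real alignment is deliberately out of scope. Molecule counting collapses
MIDs per (spot, gene) locus as connected components of the
Hamming-distance-≤1 graph — the simplest reading of "collapse allowing one
mismatch"; count-aware directional collapse would be a drop-in alternative
but is not the default.

The phantom's chip barcodes are drawn from a code with guaranteed minimum
pairwise Hamming distance 4 (base-4 index digits written three times plus
a checksum base, seed-permuted), so one-mismatch correction is provably
unambiguous and the demultiplexing recovery property (≥ 99 % of reads at
2 % barcode error, zero misassignments) is structural rather than
statistical.

## Binning, QC, normalisation, clustering, markers

Spots are summed over `bin_size × bin_size` squares
(`bin = floor(index / bin_size)`); at the 0.5 µm pitch, bin50 squares are
25 µm and bin200 squares 100 µm. QC drops bins with fewer than 3 detected
genes or mitochondrial percentage strictly above 20 %, and genes detected
in fewer than 3 bins ("minimum genes by counts" is read as a
min-cells-style gene filter; the filters iterate to a fixed point so the
operation is idempotent). An optional tissue mask drops off-tissue bins
first — the analogue of restricting analysis to MIDs under the tissue
area; ambient off-tissue bins otherwise dilute cluster-versus-rest fold
changes.

Sections of a batch are merged before clustering so cluster identities are
shared across sections. Normalisation scales each bin to the median
per-bin total (the target is a parameter) and applies `log1p`. Clustering
runs PCA, a shared-nearest-neighbour graph (Jaccard edge weights over
k-nearest-neighbour sets, pruned below 1/15), and Leiden with the
modularity objective at resolution 1.0, all seeded. The package default is
`n_neighbors = 25`: bin-level data is strongly spatially autocorrelated,
and with smaller neighbourhoods the modularity objective occasionally
splits a homogeneous compartment in two; across a dozen phantom seeds,
k = 25 recovers the planted compartments with adjusted Rand ≥ 0.94 while
k = 15 failed one seed in twelve. Harmony-style latent batch correction is
a no-op stub by design.

Marker genes are ranked per cluster and section with a from-scratch
two-sided Wilcoxon rank-sum test (normal approximation with tie
correction, no continuity correction; it matches
`wilcox.test(exact = FALSE, correct = FALSE)` to 1e-10, which the tests
use as an independent oracle). The fold change is
`log2((mean expm1 in-cluster + 1e-9) / (mean expm1 rest + 1e-9))` on
normalised data. A gene is selected for a cluster iff `p < 0.01` and
`log2FC > 1` in **every** section of the batch; p-values are raw (as the
selection rule states), with BH-adjusted values reported alongside.

## MSI

imzML (both the continuous and the processed dialect) is read and written
directly — the index XML plus the binary `.ibd` with 64-bit float arrays —
because no installed R package handles the imaging dialect. Ion images sum
centroid intensities within a ppm window; the stated "peak width" (15 ppm
for metabolites, 10 ppm for glycans and peptides) is interpreted as the
*full* window, i.e. ±width/2, and the alternative reading is a parameter.
Pixel aggregation within a window is a sum, preserving intensity linearity
into the voxel aggregation stage. Adduct annotation derives neutral masses
from observed m/z using exact particle masses (proton 1.007276466879 u,
electron 5.48579909e-4 u, Cl/Na/K monoisotopic masses) for
[M−H]⁻/[M]⁻/[M+Cl]⁻ in negative mode and [M+H]⁺/[M+Na]⁺/[M+K]⁺ in
positive mode, reporting all matches within tolerance sorted by |ppm
error|. Manual peak picking is replaced by accepting a curated peak list;
`propose_peaks()` is a labelled convenience that clusters pooled centroids
by ppm and thresholds on a signal-to-noise multiple of the weakest
cluster's mean (with few, mostly-real peaks a median-based floor would
itself be signal).

## Immunofluorescence

Tissue segmentation thresholds each rule channel (keratin 8/18 → tumor,
COL1A1 → stroma; Otsu by default) after Gaussian smoothing with replicate
boundary handling (default 10 µm), which merges punctate cell staining and
diffuse compartment staining into one tissue-scale response while being
symmetric about compartment boundaries, hence boundary-preserving. Pixels
go to the compartment with the maximal super-threshold response. Both
compartments are then eroded by 50 µm and the union of eroded-away tissue
pixels is the interface — exactly 100 µm wide across a straight boundary.
Erosion uses the Euclidean distance transform (`distance > r`) rather than
a disc structuring element: it is exact for straight boundaries and
sub-pixel-consistent on curves, and because the transform treats
out-of-image space as foreground, compartments are not eroded from the
image border (the field of view is a crop of larger tissue).

Cell segmentation is a deterministic classical pipeline replacing the
proprietary pretrained segmenter: Gaussian smooth → Otsu → distance
transform → watershed → area filter, with cell bodies grown from nuclei by
constrained propagation so neighbours clip each other. Phenotyping uses,
per cell and channel, the mean of the pixels at or above the cell's 80th
intensity percentile (the "top 20 % of pixel values"; scale-equivariant by
construction; cells under 5 pixels fall back to the plain mean and are
flagged), k-means clustering of the feature matrix, and naming by the
dominant marker. Autofluorescence subtraction is an optional per-channel
background subtraction clipped at zero.

## Voxel indexing, registration, aggregation

`build_voxel_index()` assigns consecutive indices in row-major bin order,
one channel per Leiden cluster, and refuses more than 65535 voxels (the
16-bit indexing contract). Landmark registration is a least-squares affine
fit (exact for three non-collinear pairs; residual RMS reported).
Label/index rasters are warped by inverse-mapping nearest-neighbour
resampling, which can never invent label values; bilinear interpolation is
allowed for intensity rasters only. The reference frame is the chip's
micron coordinate system. Voxel membership uses half-open intervals
`[x, x + side)` so every MSI pixel centre and cell centroid lands in at
most one voxel; a voxel covered by no MSI pixel is missing (`NA`), not
zero. Per-cluster summaries (mean, variance, quartiles, with non-missing
n) support the "which clusters are enriched for this peak / this
phenotype" readout.

## 3D stack

Registered sections are stacked with their Z centre positions and
resampled to isotropic voxels (default 0.23 µm, matching the imaging XY
pixel): XY by nearest neighbour at the exact pitch ratio, Z by filling
each output slice from the nearest section, with slice count
`floor(depth / voxel)` — 85 slices for a 19.6 µm depth. Depth is
thickness-inclusive (top of first section to bottom of last) and
overridable, since a stated crop depth need not equal the geometric stack
depth. Cross-section proximity uses Euclidean distance with ΔZ equal to
the difference of section Z centres, so cells at the same XY position in
sections 20 µm apart are 20 µm apart in 3D.

## The phantom: what it emulates and what it does not

The generator realises a tumor nodule in stroma inside a tissue disk
(alternative geometries: uniform, vertical split), with the interface
defined as all points within 50 µm of the tumor–stroma boundary. Defaults
follow the workflow's nominal acquisition conditions: 3 analysed sections of 5 µm thickness spaced
10 µm centre-to-centre (the spacing is a parameter because an
every-third-section layout implies 15 µm), 20 µm cells placed in 3D so one
cell spans ~4 consecutive contiguous sections, mitochondrial read fraction
1 % (under the reported < 2 %), microbial fraction 0.5 %, barcode error
rate 1 %, low-quality-MID rate 2 %, and per-modality misalignments of a
few degrees and ~10 µm. Gene programs plant six marker genes per
compartment at a 4-fold rate (log2FC = 2) over 18 housekeeping genes, with
per-compartment program totals balanced so library-size normalisation does
not distort the planted folds (a real composition effect the tests would
otherwise re-discover). Analyte maps plant a stroma/interface-enriched
peak, a tumor-enriched peak, and a uniform peak.

Tests and the pipeline default run the phantom chip at a 5 µm spot pitch
with `bin_size = 5` — the physical bin side (25 µm) is identical to bin50
at 0.5 µm pitch, while the binning arithmetic itself is additionally
tested at the native pitch. Problem sizes throughout (120×120-spot chips,
~1500 bins over three sections, hundreds of cells per section) were chosen
as the smallest at which the recovery properties are comfortably stable.

The phantom does **not** emulate optics (no PSF, no chromatic shifts),
isotopic envelopes or mass-calibration drift, FFPE chemistry artifacts,
segment-level deformations (misalignments are affine only), or realistic
ambient-RNA composition. Passing tests therefore demonstrate the
correctness of the *computational* contracts — demultiplexing, collapse,
clustering recovery under the planted effect sizes, window arithmetic,
registration and aggregation — not robustness to every failure mode of
real tissue data.

## Numerical choices and degenerate inputs

Grids use half-open pixel intervals with the origin at top-left; spot
indices are 0-based with physical position `index × pitch`. Resampled grid
sizes use `floor(n · scale + 1e-9)` to absorb binary-float artifacts in
pitch ratios. The Wilcoxon variance uses the tie-corrected form and
returns p = 1 when the variance collapses. `kmeans` falls back to
one-cluster or one-cluster-per-cell when the cell count is at or below the
requested k. Blank DAPI images yield zero cells (not an error); an empty
QC result, an empty tissue mask, an all-removed bin set, collinear
landmarks, singular affines, over-capacity voxel grids and unknown config
keys all raise immediate, named errors. All stochastic steps derive their
streams from a single user seed; two runs of the pipeline with the same
configuration produce byte-identical artifacts.

## Known limitations

Registration is affine-only and landmark-driven (no intensity-based or
deformable refinement); the toy aligner cannot measure splice-aware or
mismatch-tolerant mapping behaviour; Leiden determinism is tied to R's
RNG stream as used by igraph, so cluster *numbering* may differ across
igraph versions even when the partition does not; and the imzML writer
emits the minimal standards-shaped subset of the format (sufficient for
round-trip and for pyimzML-style readers, but not a full mzML
implementation).
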