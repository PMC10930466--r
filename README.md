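# spatialfuse

Integration of targeted and non-targeted spatial omics measured on serial
tissue sections: submicron spatial transcriptomics (barcoded capture chip),
mass spectrometry imaging (MSI), and sequential multiplex
immunofluorescence (seqIF), fused on a common "Leiden voxel" coordinate
frame and reassembled into an isotropic 3D volume.

## Who this is for

Groups profiling one FFPE block with several spatial platforms — each on a
*different* serial section — who need the per-location molecular readouts
of all platforms in one table. The package covers the full computational
path and ships a ground-truth synthetic tissue phantom, so the pipeline is
testable end to end without any external data.

## The method

1. **Demultiplexing.** Read 1 = 25-base spatial barcode (CID) + 6-base
   molecular identifier (MID, positions 26–31). CIDs match the chip layout
   exactly or by a *unique* 1-mismatch correction; MIDs with an N or more
   than 2 bases below Q10 are filtered. Read 2 is assigned by transcript
   tag; hits with MAPQ ≤ 10 are discarded, non-host tags feed a microbial
   taxon partition. Molecules are counted per (spot, gene) as connected
   components of the Hamming ≤ 1 graph on MIDs.
2. **Binning and clustering.** Spots are summed over bins (bin50 at 0.5 µm
   pitch = 25 µm squares); bins are QC-filtered (≥ 3 genes, mito ≤ 20 %,
   genes in ≥ 3 bins), sections merged, normalised to the median bin total,
   `log1p`-transformed, and clustered with PCA → shared-nearest-neighbour
   graph → Leiden (modularity, resolution 1.0). Markers per cluster are
   selected by a Wilcoxon rank-sum test at `p < 0.01` and `log2FC > 1` in
   every section.
3. **Leiden voxels.** Every clustered bin becomes a voxel with a globally
   unique 16-bit index, one image channel per cluster — the indexed raster
   other modalities are registered to (least-squares landmark affines;
   nearest-neighbour warping for label rasters).
4. **MSI.** imzML in/out (continuous and processed), ion images as sums in
   a ppm window (full width 15 ppm for metabolites, 10 ppm for glycans and
   peptides), adduct annotation via exact particle masses
   ([M−H]⁻/[M]⁻/[M+Cl]⁻ negative; [M+H]⁺/[M+Na]⁺/[M+K]⁺ positive).
5. **seqIF.** Rule-based tissue segmentation (keratin → tumor,
   COL1A1 → stroma) with both compartments eroded by 50 µm; the
   eroded-away band is the tumor–stroma interface (exactly 100 µm across a
   straight boundary). DAPI watershed cell segmentation; per-cell features
   are the mean of the top 20 % of pixel intensities per channel;
   phenotypes by k-means, named after the dominant marker.
6. **Aggregation and 3D.** Per voxel: gene expression (inherently aligned),
   mean MSI intensity of warped pixel centres, phenotyped cell counts
   (half-open voxel intervals; empty MSI voxels are `NA`). Registered
   sections stack into an isotropic volume (0.23 µm voxels;
   `floor(depth/voxel)` slices — 85 for 19.6 µm), and cross-section cell
   proximities use section Z centres (10 µm spacing ⇒ layer 1 vs layer 3
   cells at the same XY are 20 µm apart).

## Worked example

Phantom → reads → matrix → bins → Leiden → markers → voxels → MSI
aggregation:

```r
library(spatialfuse)

cfg <- phantom_config(seed = 11)           # tumor nodule in stroma, 3 sections
ph  <- make_phantom(cfg)
lay <- emit_chip_layout(120, 120, pitch_um = 5, seed = 11)
mask <- ph$compartments[[1]] > 0
attr(mask, "pitch_um") <- attr(ph$compartments[[1]], "pitch_um")
ref <- toy_reference(rownames(cfg$gene_programs), seed = 11)

binned <- lapply(1:3, function(s) {
  rd <- emit_stereo_reads(ph, s, lay, depth = 3, reference = ref)
  m  <- build_matrix(rd$read1, rd$qual1, rd$read2, lay, ref, section = s)
  if (s == 1) print(qc_summary(m, mask, bin_size = 40L))
  qc_filter(bin_spots(m, 5), tissue_mask = mask)
})
#> qc_summary: 97.1% MID under tissue | median/bin40: 3675 reads, 3675 MID,
#>             36 genes | mito 1.15% | 143 microbial MID

tx  <- preprocess(binned)
lab <- cluster_bins(tx, seed = 11)
table(lab$cluster)
#>   1   2   3
#> 659 374  71

mk <- rank_and_select(tx, lab$cluster)
head(mk[mk$selected, c("cluster", "gene", "p_value", "log2fc")], 4)
#>   cluster gene      p_value   log2fc
#> 1       1 STR6 1.273232e-44 1.724586
#> 2       1 STR3 1.016424e-42 1.776926
#> 3       1 STR5 8.304833e-41 1.696305
#> 4       1 STR1 1.296131e-40 1.703372

v   <- build_voxel_index(lab[lab$section == 1, ], bin_size = 5, pitch_um = 5)
#> leiden_voxel_image: 368 voxels, 3 clusters, side 25.0 um
msi <- emit_msi(ph, 1, c(1077.361), noise_sd = 0.5)
ion <- extract_ion_image(msi, 1077.361, 10)
vt  <- aggregate_per_voxel(v, ion_images = list("1077.361" = ion),
                           msi_transform = ph$truth_transforms$msi)
cluster_stats(vt, "mz_1077.361")
#>   cluster   n     mean       var      q25    median       q75
#> 1       1 223 9.730891 1.9450967 9.542171 10.010312 10.302189
#> 2       2 123 7.788215 1.4386718 7.705912  7.991285  8.262553
#> 3       3  22 1.934135 0.3090738 1.767135  1.848513  2.090816
```

Reading the output: the three Leiden clusters recover the planted tumor,
stroma and interface compartments (cluster sizes 71/659/374); each
cluster's selected markers are exactly the genes planted for its
compartment at a 4-fold rate; and the stroma-planted m/z 1077.361 peak
(truth intensities 10/8/2 in stroma/interface/tumor) is quantified per
voxel through the ground-truth misalignment at cluster means 9.7 / 7.8 /
1.9 — highest in the stroma-matching cluster, as it should be.

A one-shot end-to-end run with artifact output and a content-hash
manifest:

```r
run_pipeline(list(seed = 11), out_dir = "out")   # or inst/cli/spatialfuse.R
```

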