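Package: spatialfuse
Title: Integration of Spatial Transcriptomics, Mass Spectrometry Imaging and
    Sequential Immunofluorescence on Serial Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building a common coordinate frame across targeted and
    non-targeted spatial omics modalities measured on serial tissue sections.
    Covers spatial barcode demultiplexing and UMI collapse for
    submicron-resolution spatial transcriptomics chips, bin-level QC,
    normalization, Leiden clustering and Wilcoxon marker selection,
    imzML-based mass spectrometry imaging ion-image extraction and adduct
    annotation, immunofluorescence tissue/cell segmentation with
    erosion-defined interface zones and top-quintile phenotyping, landmark
    affine registration with nearest-neighbour label warping onto a 16-bit
    indexed "Leiden voxel" image, per-voxel cross-modal aggregation, and
    isotropic 3D reconstruction of the section stack. A synthetic tissue
    phantom generates all three modalities with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    grDevices,
    methods,
    EBImage,
    tiff,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
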