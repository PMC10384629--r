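Package: aluckit
Title: Design Toolkit for Artificial Copepod Luciferase Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for engineering artificial copepod-luciferase (ALuc)
    variants from single-sequence alignment insights. A luciferase is
    partitioned into its flexible N-terminal region and two homologous
    catalytic domains, the three regions are stacked into a self-alignment,
    vacant (gap) spans are detected, and compensation peptide blocks derived
    from the homologous donor rows are inserted to generate nested sibling
    variant series. The package also assembles codon-optimized cDNA
    constructs (expression inserts, single-chain molecular strain probes,
    protein fragment complementation probes), builds neighbor-joining trees
    from alignment identity distances, summarises bioluminescence emission
    spectra (peak wavelength, FWHM, red spectral fraction), computes
    sequence properties (molecular weight, theoretical isoelectric point),
    and measures inter-side-chain distances on atomic coordinate models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    ape,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
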