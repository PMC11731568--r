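Package: tsrkeys
Title: Triangle-Key Fingerprints for Alignment-Free Comparison of
    Molecular 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts protein backbones, pigment cofactors and single
    amino acids into integer triangle-key fingerprints (TSR keys): every
    triple of atoms defines a triangle whose ordered vertex labels,
    binned longest edge and binned midpoint angle are encoded as one
    integer, and a molecule becomes a key-frequency vector.  Provides
    Generalized and Normalized Jaccard similarity between key vectors,
    common/specific key mining with key-to-triangle back-mapping,
    average-linkage clustering, classical multidimensional scaling and
    the adjusted Rand index, plus two baseline comparators (ultrafast
    shape recognition descriptors and Kabsch-superposition RMSD).
    Includes cofactor binding-site contact analysis tools, a packaged
    photosystem I cofactor annotation table, deterministic synthetic
    structure generators for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools,
    ape,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
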