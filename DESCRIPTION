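Package: bundlefold
Title: Enumeration of Single-Chain Three-Helix Bundles from Alpha-Alpha
    Hairpin Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale analysis of which combinations of alpha-helix
    lengths and loop conformations fold into compact single-chain
    three-helix bundles. Provides ABEGO coarse-graining of backbone
    torsions, helix-loop-helix fragment extraction with packing
    handedness geometry (crossing angle and inter-helix dihedral),
    Crick-parameterized clockwise/counter-clockwise reference decoys,
    blueprint-driven sequence-independent backbone building with a
    TM-score folded criterion, Kabsch-Sander hydrogen-bond analysis of
    hairpin loops, and a synthetic fragment generator with exact truth
    labels.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
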