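Package: keystrings
Title: Alignment-Free Phylogenetics from Key Amino-Acid K-Strings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free phylogenetic analysis of protein sets (typically the 13
    mitochondrial protein-coding genes) via composition vectors of amino-acid
    K-strings with (K-2)-order Markov background subtraction. Implements
    variance-based dimensional reduction of the composition-vector matrix to
    extract "key" K-strings (the L-curve critical point at 90% reduction of the
    maximum column variance), broad and taxon-specific key-set extraction with
    subgroup intersections, cosine-distance neighbor-joining trees with
    gene-resampling bootstrap support, key-set sharing/bias tables, residue
    composition profiles, a chi-square test of observed versus Markov-expected
    K-string frequencies, and sliding-window conservation analysis that maps key
    K-strings back onto aligned sequences. A clade-structured sequence simulator
    with known ground truth supports testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
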