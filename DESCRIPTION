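Package: circplasmid
Title: Circular Plasmid Detection and Typing for Plasmidome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-assembly plasmidome analysis for shotgun-sequenced plasmid
    DNA libraries. Detects complete circular plasmids among assembled
    scaffolds using three criteria (minimum scaffold length, terminal
    direct-repeat homology scored with a Karlin-Altschul E-value, and
    junction-spanning read-pair support), removes 16S rRNA-carrying
    scaffolds and spiked control-plasmid sequence, classifies plasmids by
    mobility (conjugative / mobilizable / nonmobilizable), relaxase MOB
    family and incompatibility group, and summarizes the results. Ships a
    synthetic-community generator (circular templates linearized with
    terminal repeats, paired-end read simulation, chromosomal and
    rRNA-carrying decoys, spike-in controls) plus a naive exact-seed read
    mapper so the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
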