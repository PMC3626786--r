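Package: duplexscan
Title: Sliding-Window Detection of Long-Range RNA Duplex Elements in mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects non-hairpin, long-range double-helical elements
    (notably GC-rich helices) in mRNA secondary structures. Transcripts
    are cut into overlapping windows, each window is folded by a
    pluggable backend (precomputed CT or dot-bracket files, a live
    folding engine, or a deterministic fixture), and the predicted
    structures are scanned for uninterrupted stacked helices that
    satisfy length, strand-distance, linker-pairing and base-composition
    criteria. Motifs are mapped to transcript coordinates, deduplicated
    across overlapping windows and suboptimal structures, assigned to
    functional mRNA regions (5'-region, remaining CDS, 3'-UTR), and
    reported as per-100-nt frequencies with distance statistics. Includes
    composition-preserving shuffled controls, synthetic transcripts with
    planted duplexes for offline testing, and a local folding-potential
    profile.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
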