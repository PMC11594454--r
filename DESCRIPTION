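Package: pbdqc
Title: Perfect-Read Coverage Quality Control for Genome Assemblies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembly quality control built around perfectly mapped long
    reads. Classifies read-to-assembly alignments (PAF) as full-length per
    platform-specific end tolerances, computes sliding-window perfect-read
    coverage against per-chromosome mean depth to flag candidate misjoins
    (depth loss) and collapsed repeats (depth gain), censuses telomeric
    TTAGG/CCTAA arrays and assembly gaps, triages reads around gaps and
    chromosome ends for local re-assembly and validates candidate patch
    contigs, and filters whole-genome alignments into collinearity blocks
    with inversion calls. Ships a misassembly simulator (toy genomes with
    telomeres and repeat arrays, injected structural errors with truth
    coordinates, error-free long reads, and truth-lifted alignments) so
    every detector is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
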