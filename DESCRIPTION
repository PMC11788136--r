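Package: igloci
Title: Immunoglobulin Locus Annotation and IgH CDR3 Repertoire Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating immunoglobulin (IgH, Igk, Igl) germline loci
    in genomic assemblies and for analysing IgH CDR3 repertoires from amplicon
    sequencing. Implements recombination signal sequence (RSS) scanning against
    the heptamer/nonamer consensus with the 12+/-1 and 23+/-1 spacer rule,
    structural detection of V, D, J and C gene segments, IMGT-style F/ORF/P
    functionality classification with defect codes, 75 percent-identity family
    clustering and 5'-to-3' locus naming, construction of a segmented germline
    reference with CDR3 anchor positions, read alignment and CDR3 extraction
    with junction (trimming/insertion) bookkeeping, clonotype assembly, and
    repertoire statistics (inverse Simpson diversity, analytic rarefaction,
    clonal and rare proportions, repertoire overlap, length and gene-usage
    distributions). A ground-truthed synthetic-data generator produces toy
    germline loci and simulated V(D)J amplicon repertoires for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
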