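Package: targasm
Title: Targeted Transcript Assembly and Annotation from RNA-seq Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts genes of interest directly from raw RNA-seq reads
    without a global transcriptome assembly. Reads are quality- and
    adapter-trimmed, optionally binned against user-supplied reference
    genomes with a canonical k-mer classifier, recruited by translated
    homology to protein queries (seed-and-extend plus nucleotide k-mer
    enrichment), assembled with a small de Bruijn graph assembler, and
    annotated: matching transcripts are retained, open reading frames are
    located and classified under the appropriate NCBI genetic code, and
    the best-scoring ORF per transcript is reported as its coding
    sequence in GFF3 and FASTA form. A seeded simulator generates
    paired-end read sets with planted target transcripts and a
    ground-truth manifest for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'targasm-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'align.R'
    'seq-io.R'
    'genetic-code.R'
    'annotate.R'
    'assemble.R'
    'filter.R'
    'ini.R'
    'recruit.R'
    'strategy.R'
    'trim.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
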