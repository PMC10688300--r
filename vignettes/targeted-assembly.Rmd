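---
title: "Targeted transcript assembly and annotation with targasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted transcript assembly and annotation with targasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targasm)
```

## The problem

Most questions about a gene family do not need a whole-transcriptome
assembly. Given RNA-seq reads and a handful of protein sequences
describing the family of interest, it is enough to find the reads that
look like those proteins, assemble only them, and annotate the result.
targasm implements that workflow end to end with self-contained
algorithms: quality/adapter trimming, reference-based read binning,
translated-homology read recruitment, local de Bruijn assembly, and ORF
annotation under the appropriate NCBI genetic code. A configuration-driven
pipeline (`runPipeline()`) chains the stages, checkpoints completed work,
and never repeats a stage whose inputs and parameters are unchanged.

## The stages and their models

### Trimming

`trimPairs()` applies, per read and in this order: adapter clipping
(earliest position where an adapter prefix matches a read suffix with at
least `adapterMinOverlap = 8` bases and at most `adapterMaxMismatch = 1`
mismatches, or any full internal occurrence), leading/trailing clipping of
bases below Phred `leadQ`/`trailQ` (default 3), a left-to-right sliding
window (width 4, mean Phred 20) and a 36-base length floor. When a window
fails, the cut falls at the window's start and then advances over bases
that individually meet the window threshold -- the behaviour of the
standard sliding-window trimmers, and the semantics under which trimming
is idempotent. A pair survives only if both mates survive; lone survivors
become orphans, so every input read is accounted for exactly once.
K-mer-spectrum error correction is deliberately not implemented: the
assembler's `minCount` filter absorbs isolated sequencing errors, which is
sufficient at the scale of a recruited read set.

### Read binning

`buildKmerIndex()` stores, per user-supplied reference (organelle genome,
pathogen, rRNA, anything), the set of canonical 31-mers (the
lexicographically smaller of a k-mer and its reverse complement; odd k
avoids self-complementary words). `classifyReads()` counts how many of a
read pair's k-mer positions hit each reference; the winner takes the pair
if it is unique and collects at least `minFrac = 0.25` of the positions,
ties are "ambiguous", everything else passes through "unclassified" --
which is precisely the read set the downstream stages consume. One exact
k-mer classifier fills the role that read mapping and taxonomic
classification play in heavyweight pipelines: at desk scale, user-supplied
FASTA references subsume prebuilt databases, and exact canonical-k-mer
membership is both fast and strand-free. Mates are classified jointly
(summed hits) so pairs never separate. The 0.25 threshold is an invention
of this package -- no published threshold semantics exist for this role --
and is therefore configurable.

### Query-set construction

A search strategy (one INI section per gene family) names protein FASTA
files, a query length window, and a pruning identity `dedupIdentity =
0.98`. `buildQuerySet()` pools the sequences, strips terminal stops,
applies the length window, then greedily prunes: longest first (ties by
id), keeping a sequence only if its identity to everything already kept is
below the threshold. Identity is matched alignment columns over the
shorter sequence, a deliberate choice the underlying literature leaves
open; keeping the longest representative of a redundant cluster maximizes
the read diversity a query can recruit. Remote accession fetching (Pfam,
NCBI) is out of scope; `queryFetchHook()` marks where it would attach.

### Recruitment

Recruitment is two-staged, mirroring the classic translated-search +
sequence-neighbourhood design.

Stage 1 (`recruitSeed()`): every read is translated in six frames; exact
amino-acid words of length `aaWord = 4` shared with a query seed an
ungapped extension under BLOSUM62 that stops when the running score drops
`xDrop = 20` below its maximum. A pair is recruited when either mate's
best extension reaches `minScore = 50` (roughly an 11-residue perfect
match). The raw-score threshold replaces e-value statistics; it errs on
the permissive side on purpose -- downstream matching is the precise
filter -- and all three knobs are exposed. Gapped per-read alignment was
rejected for speed: reads are short enough that an ungapped x-drop is an
excellent proxy.

Stage 2 (`enrichReads()`): the canonical 25-mers of all stage-1 reads form
a bait set; one rescan of the full stream pulls in any unrecruited pair
sharing at least `minShared = 2` distinct k-mers. A single pass (not a
fixpoint iteration) is used: each additional pass mostly recruits
neighbours-of-neighbours with rapidly decaying relevance, and one pass
already extends recruitment into the untranslated ends. Duplicate ids are
kept once, so the recruited set is a proper id-keyed union.

### Assembly

`assembleTargeted()` is a single-k de Bruijn unitig assembler: canonical
31-mer counting, a `minCount = 2` count floor, iterative clipping of
dead-end tips up to `tipLen = 2k` nodes, coverage-guided popping of
bubbles whose arms share both junctions at `bubbleIdentity >= 0.95`
(isolated substitution errors and heterozygous SNPs), and spelling of
maximal non-branching paths. Contigs are reported once, in canonical
orientation (lexicographic minimum of sequence and reverse complement),
filtered at `minContigLen = 200` bases, and named `contig_N` in a fixed
order (length descending, then sequence), so identical inputs give
byte-identical FASTA. There is no paired-end scaffolding, no multi-k
iteration and no isoform enumeration -- a documented fidelity gap relative
to a full transcriptome assembler, accepted because recruited read sets
are tiny and local.

### Annotation

`matchTranscripts()` aligns each contig's six frame translations against
every query (affine Smith-Waterman, BLOSUM62, gap open 11 / extend 1,
matching the defaults of translated search tools) and keeps contigs whose
best alignment clears `matchMinScore = 60`, `matchMinIdentity = 0.40` and
`matchMinQcov = 0.50` simultaneously; the winning frame fixes the strand.
User-supplied transcriptome FASTAs pass through the same matching.

`findOrfs()` scans only the matched strand (the strand is already known
from the protein match). Complete ORFs run start-codon-to-stop (stop
included in the span, excluded from the peptide; nested starts sharing a
stop collapse to the longest). A frame whose first stop has no upstream
start yields a 5'-partial ORF from the contig edge (suppressable via
`allowPartialOrfs`); a start without a downstream stop yields a
3'-partial; a frame with neither is a single edge-to-edge "internal" ORF.
ORFs never begin at an X (N-containing codon). Alternative initiators are
opt-in through `startCodons` (default ATG only) and translate as M.

`selectCds()` resolves "highest scoring ORF" -- which the field leaves
undefined -- as the ORF with the best local-alignment score against the
query set, with ties broken by completeness (complete over partial over
internal), then peptide length, then position. With no queries the score
falls back to peptide length, so the longest ORF wins. This
query-similarity semantic is the package's single largest invented
definition and is worth knowing when comparing against other annotators.

Genetic codes: six NCBI tables (1, 2, 4, 5, 9, 11) ship as a plain-text
data file; `sourceCodeMap()` routes nucleus to table 1, plastid to 11 and
mitochondrion to 1 by default, all overridable. Codons containing N
translate to X.

`writeAnnotation()` emits the four per-strategy outputs: transcript FASTA,
GFF3 (one mRNA per transcript, one CDS per selected ORF), CDS nucleotide
FASTA (reverse-complemented for minus-strand matches) and CDS peptide
FASTA. Internally every coordinate is 0-based half-open; conversion to
GFF3's 1-based inclusive convention happens only in the writer. CDS phase
is 0 for complete ORFs and `(3 - (f mod 3)) mod 3` for 5'-partials, where
f is the reading-strand frame offset of the in-frame start; GFF phase
conventions differ between tools, so the choice is documented here and
round-trips through `rtracklayer`.

## The synthetic-data generator

`simulateDataset()` builds the kind of project the pipeline is meant for:
50 random background transcripts (500-3,000 bases), one target transcript
(5'UTR + CDS back-translated from a planted protein with uniformly chosen
synonymous codons + 3'UTR, UTRs 50-300 bases), and a 10 kb random
organelle genome as contamination. Reads are 150 bp pairs at 30x coverage
with Normal(350, 50) inserts (truncated below at the read length),
i.i.d. substitutions at 1%, and Normal(38, 2) base qualities that do not
encode the error positions -- errors are silent, as in real data. A
`truth.json` manifest records each pair's origin and the planted CDS.
All randomness flows from one seed through R's Mersenne-Twister RNG, so
outputs are byte-identical across runs and platforms.

Two generator properties are worth making explicit. First, the reading
frame is closed by an in-frame stop immediately upstream of the planted
start codon, as real 5'UTRs almost always are; without it the planted CDS
would not always be the longest complete ORF in its frame and "exact
recovery" would be ill-defined. Second, fragment placement is uniform, so
a transcript's terminal few bases are usually uncovered at 30x; exact
end-to-end transcript recovery is therefore exercised with tiled reads,
while the random-fragment simulations are judged by identity and coverage.

What the generator does not emulate: indels (substitution-only error
model, matching the dominant short-read error mode), expression
heterogeneity, strand-specific library artifacts, PCR duplicates, and
real codon usage (uniform synonymous choice). Passing tests on this
generator demonstrate the algorithms' correctness and their behaviour at
realistic error rates and coverages -- not robustness to structural
artifacts of real libraries.

## Numerical and determinism choices

* Alignment tie-breaks: among equal-scoring local alignments the first
  cell in row-major order wins (smallest end coordinates) and the
  traceback prefers substitutions over gaps; deterministic, and score
  agreement with an independent dynamic-programming oracle is asserted in
  the tests.
* Bubble-arm identity uses plain edit distance over the arm sequences
  (arms are short); equal-coverage arms are ordered by sequence.
* The classifier, enrichment and assembler all share one 2-bit canonical
  k-mer encoding (k <= 31 fits a 64-bit word).
* Degenerate inputs are contracts, not crashes: reads shorter than k are
  "unclassified"; an empty de Bruijn graph yields an empty contig list; a
  contig with no passing ORF is still written, without a CDS; an empty
  query set after pruning is an error naming the strategy.
* Test and example problem sizes -- ~50 transcripts, ~10,000 read pairs,
  single genes at 30x -- are the package's intended desk scale; every
  stage runs in seconds there.

## Pipeline behaviour

The run manifest stores, per stage, a parameter hash, the md5 of every
input file and the output paths. A stage re-runs only if any of these
changed (or `--force`); re-running an unchanged project performs zero
stage work, and a change to one strategy re-runs only that strategy.
Filtered reads land under `01-global/05-filtered-fq-data/[SAMPLE]/`
(`stopAfterFilter = TRUE` ends the pipeline there, leaving the binned
FASTQ files as the product); per-gene results land under
`02-strategies/[STRATEGY]/`. The pipeline refuses to overwrite files it
did not create. SRA accessions in the configuration are recognized and
rejected with a pointer to external fetch tooling -- network retrieval is
out of scope throughout.

## Known limitations

* Recruitment scores carry no significance statistics; thresholds are raw
  scores and should be tuned permissively.
* The assembler reports unitigs only: alleles more divergent than
  `bubbleIdentity`, paralogs, and isoforms sharing k-mers come out as
  separate (or truncated) contigs rather than resolved paths.
* One CDS is reported per transcript even under score ties (the cascade
  makes the choice deterministic).
* Functional annotation is out of scope; `orfs_aa.fasta` is the hand-off
  point for downstream protein-domain tools.
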