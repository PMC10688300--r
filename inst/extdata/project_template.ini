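# Project configuration template. SRA accessions are rejected: provide
# local FASTQ paths (plain or .gz).
[project]
name = my_project
output_dir = /path/to/output

[input]
sample_name = sample1
reads_1 = /path/to/reads_1.fastq.gz
reads_2 = /path/to/reads_2.fastq.gz
# transcriptomes = /path/to/assembled1.fasta; /path/to/assembled2.fasta

[filter]
# any number of label = FASTA reference pairs, e.g.:
# mitochondrion = /path/to/mt_genome.fasta
# plastid = /path/to/cp_genome.fasta
# virus = /path/to/pathogen.fasta

[filter_sources]
# mitochondrion = mitochondrion
# plastid = plastid

[trim]
window = 4
window_minq = 20
lead_q = 3
trail_q = 3
min_len = 36
# adapters = /path/to/adapters.fasta

[classify]
k = 31
min_frac = 0.25

[seed]
aa_word = 4
min_score = 50
x_drop = 20

[enrich]
nt_k = 25
min_shared = 2

[assembly]
k = 31
min_count = 2
bubble_identity = 0.95
min_contig_len = 200
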