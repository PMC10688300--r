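# Search-strategies template: one section per gene / gene family.
# All keys are optional except query_fasta_paths; defaults shown.
[my_gene_family]
query_fasta_paths = /path/to/queries.fasta
min_query_len = 10
max_query_len = 100000
dedup_identity = 0.98
match_min_score = 60
match_min_identity = 0.40
match_min_qcov = 0.50
orf_min_len = 30
orf_max_len = 100000
start_codons = ATG
allow_partial_orfs = true
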