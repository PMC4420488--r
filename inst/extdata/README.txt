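Synthetic example data (no real sequencing reads).

synthetic_pool.fasta   12 random 20-25 nt RNA sequences acting as a tiny
                       defined reference pool (generated by generate_pool()
                       with seed 42).
synthetic_mix.tsv      a non-equimolar concentration assignment for the pool.
adaptors.fasta         the package's default A1-like 3'(DNA)/5'(RNA) adaptor
                       pair.
synthetic_reads.fastq  300 simulated reads (uniform efficiencies) built as
                       5'-adaptor + insert + 3'-adaptor by simulate_library().
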