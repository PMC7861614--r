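{
  "simulate": true,
  "seed": 1,
  "kmer_length": 50,
  "bin_width": 1000,
  "sim": {
    "n_chrom": 3,
    "chrom_length": 80000,
    "mito_length": 5000,
    "insertions_per_family": 1,
    "consensus_length_range": [1000, 2000],
    "min_insertion_gap": 8000,
    "domain_width": 6000,
    "n_genes": 60,
    "chip_replicates": 2,
    "chip_depth": 30000,
    "rna_replicates": 3,
    "rna_depth": 200000,
    "seed": 1
  }
}
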