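# example dilution-series spec: 10-genome mixture, graded cassette contamination
n_genomes = 10
genome_length = 20000
alpha = 6
n_reads = 2000
read_length = 35
error_rate = 0
cassette = AAAAAAAAAAAA
contamination_fractions = 0,0.01,0.05,0.3,0.7
seed = 1
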