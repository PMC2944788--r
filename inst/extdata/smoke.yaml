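name: smoke
seed: 7
population:
  n_ind: 300
  n_snp: 500
  n_chrom: 3
  chrom_length_morgans: 1.2
  ne: 60
  n_generations: 120
  n_sires: 15
  n_discovery: 200
  n_validation: 100
qc:
  min_call_rate: 0.9
  min_maf: 0.02
  hwe_p_min: 1.0e-5
trait:
  archetype: black_like
  h2: 0.74
gwas:
  p_disc: 1.0e-4
  p_val: 0.05
prediction:
  bayesa:
    n_iter: 600
    burn_in: 150
    thin: 3
segvar:
  segment_size: 50
  n_perm: 2
theory:
  N: 756
  h2: 0.63
  ne: 100
  genome_morgans: 30
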