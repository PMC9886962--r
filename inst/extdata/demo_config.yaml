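# Demo pipeline configuration: simulated inputs at desk scale.
seed: 42
simulate:
  n_pops: 8
  n_per_pop: 8
  n_loci: 500
  n_chrom: 2
  chrom_length_bp: 500000
  fst: 0.3
  n_adaptive: 10
  adaptive_slope: 1.5
  block_len_bp: 5000
  missing_rate: 0.02
structure:
  kmin: 1
  kmax: 3
  runs: 3
  n_init: 1
  focal_ancestry: null
dapc:
  max_k: 4
tree:
  boot: 100
gea:
  axes: "fixed:4"
ld:
  max_dist: 50000
  bin: 2000
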