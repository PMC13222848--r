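# Scarabaeoidea-like synthetic scenario: a 200-tip dated tree ~184 My deep
# (branch lengths in units of 10^8 years), root karyotype 9 autosomes + XY,
# and move rates of realistic magnitude (0.002-0.007 per My). 17.5% of tips
# carry a second, conflicting karyotype record.
model: scs
seed: 1
out_dir: scarab_like_out
simulate:
  n_tips: 200
  n_trees: 5
  birth: 3.0
  death: 0.5
  depth: 1.84
  root_k: 9
  root_system: XY
  k_min: 1
  k_max: 25
  multi_record_fraction: 0.175
  jitter_sd: 0.1
  params:
    fission: 0.3
    fusion: 0.7
    sa_fusion: 0.6
    reversion: 0.2
mcmc:
  generations: 100
  burn_in: 0.5
  prior_rate: 2
mapping:
  maps_per_sample: 1
sa_null:
  formulation: haploid
  include_neo: false
hpd_mass: 0.95
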