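# Example pipeline configuration for run_pipeline()/run_config().
# Point fasta/labels at an aligned FASTA and its sidecar label table
# (id<TAB>population<TAB>year), or pass an alignment object directly.
out_dir: phylodem_out
temporal_replicates:
  SIN: [SIN03, SIN04, SIN08]
  OAX: [OX03, OX05]
  CH: [CH03, CH04]
groups:
  SIN: north
  SIN04: north
  MICH02: north
  OAX: central
  CH: central
  PE05: south
alpha: 0.05
n_perm: 1000
n_boot: 200
fu_sims: 1000
gamma_alpha: 0.4
rate: 3.6e-8
L: 648
generation_years: 2
nj_bootstrap: 100
seed: 1
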