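# Example pipeline configuration: a shortened version of the first
# design for quick runs. Load with read_config() and pass the design
# section to make_design(overrides = ...).
design:
  n_blocks_per_condition: 2
  trials_per_block: 20
  n_baseline_per_block: 10
fit:
  n_particles: 200
  restarts: 3
seeds:
  master: 1
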