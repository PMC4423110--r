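# End-to-end demo: simulate a small cohort with planted truth, then run
# every analysis stage. Minutes-scale on one core.
#   r <- run_pipeline(system.file("extdata", "demo_config.yaml",
#                                 package = "methblocks"), "demo_run")
seed: 11
simulate:
  genome:
    block_delta: 0.09
  n_per_group: 6
  wgbs_n_per_group: 3
array_blocks:
  n_perm: 200
dmrs:
  n_perm: 200
wgbs: {}
enrichment:
  n_sets: 500
summaries:
  target_r2: 0.8
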