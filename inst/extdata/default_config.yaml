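# Default hmcall pipeline configuration: simulated HP1-mutant hippocampus
# study (eight conditions: WT/HP1bKO/HP1gKO/DKO x young/aged) with the
# shipped effect structure, contrasting aged double-knockout against aged
# wild type on both channels.
seed: 1
outdir: hmcall_run
simulation:
  n_sites: 10000
  n_replicates: 3
contrasts:
  - name: DKO_aged_vs_WT_aged
    group_a: WT_aged
    group_b: DKO_aged
    channels: [5mC, 5hmC]
  - name: HP1bKO_aged_vs_WT_aged
    group_a: WT_aged
    group_b: HP1bKO_aged
    channels: [5mC, 5hmC]
thresholds:
  min_coverage: 10
  min_diff_pct: 25
  q_threshold: 0.05
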