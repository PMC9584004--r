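# Small demonstration run: a 150 x 150 m hillslope with 10 platforms.
seed: 7
out_dir: charcoalscape-demo
scenario:
  extent_m: [150.0, 150.0]
  n_platforms: 10
  n_confusers: 15
ordinate:
  n_plots: 60
  n_perm: 199
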