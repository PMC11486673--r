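# Demo run configuration: simulate a noisy phantom, analyse it with the
# measured-AIF route, and report VOI statistics.
mode: all
out_dir: dce_demo_run
phantom:
  dims: [32, 32, 8]
  tumour_centre: [24, 16, 4]
  tumour_radius: 3.6
  artery_corner: [15, 5, 1]
  artery_size: [2, 2, 8]
  sigma: 0.05
  seed: 1234
aif:
  k: 10
  hct: 0.45
  pv_factor: 1
kinetics:
  n_starts: 5
  seed: 1234
  r1: 3.7
  rbf_estimator: fp
stats:
  sidedness: two
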