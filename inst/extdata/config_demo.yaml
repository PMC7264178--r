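# Demonstration configuration: a desk-scale four-genotype experiment with
# an eraser-heavy differential signal and strong double-mutant rescue.
sim:
  n_genes: 600
  n_regions: 400
  baseline_logmean: 5.3
  dispersion: 0.02
  frac_A_up: 0.02
  frac_A_down: 0.08
  frac_B_up: 0.2
  frac_B_down: 0.05
  frac_opposite_overlap: 0.3
  frac_same_overlap: 0.15
  effect_logmean: 0.9
  effect_logsd: 0.3
  frac_rescued: 0.6
  attenuation_a: 0.3
  seed: 2026
slope_method: ols_origin
dispersion_method: feature
seed: 2026
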