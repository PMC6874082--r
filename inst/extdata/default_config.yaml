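# Default run configuration (all values shown are the package defaults;
# any key may be omitted).
seed: 20191121
task:
  n_rounds: 5
  deltas: [0.25, 0.15, 0.20, 0.15, 0.25]
  true_count_min: 50
  true_count_max: 60
bank:
  n_adults: 24
  n_students: 14
  n_iterations: 6
cohort:
  n_participants: 256
  school_counts: {school_A: 149, school_B: 107}
  household_counts: {nuclear: 108, extended: 148}
  gender_counts: {male: 125, female: 131}
  age_mean: 13.38
  age_sd: 0.88
  age_range: [11, 15]
  p_aunts_uncles: 0.25
agent:
  bias_sigma: 0.15
  p_stay: {peer: 0.285, adult: 0.255}
  p_copy: {peer: 0.165, adult: 0.195}
  p_contrarian: 0.022
  p_overshoot: 0.056
  compromise_shape: [2.52, 2.48]
  adult_shift: 0.0107
  household_shift: 0.0
analysis:
  filter_policy: omit
  alpha: 0.05
  drop_school: false
  glmm_rounds: valid
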