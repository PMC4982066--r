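{
  "covariate_only_0.2": {
    "theta_cont": [-1.5711841871962, 0.830757353454828, 0],
    "theta_bin": [-1.57492958474904, 0.834026638418436, 0]
  },
  "covariate_only_0.5": {
    "theta_cont": [0.00271002296358347, 0.659806463867426, 0],
    "theta_bin": [0.000181733630597591, 0.660856511443853, 0]
  },
  "outcome_dependent_0.2": {
    "theta_cont": [-2.43701472412795, 0.936058584600687, 1.70938539078588],
    "theta_bin": [-2.56125185173005, 0.927009504288435, 0.545695741108258]
  },
  "outcome_dependent_0.5": {
    "theta_cont": [-0.507647884078324, 0.725483398884535, 1.35763291819288],
    "theta_bin": [-0.625663320533931, 0.724119406193495, 0.432392164910257]
  }
}
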