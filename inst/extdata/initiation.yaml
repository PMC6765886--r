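# Initiation/continuing-use scenario: cigar users prevented in one cohort of
# 18 year olds under a nationwide flavored-cigar prohibition.
model_kind: initiation
inputs:
  # 18 year olds in the US cohort.
  cohort_size: 4200000
  # Current (every-day/some-day) cigar-use prevalence at age 18.
  # A past-30-day alternative of 0.131 is supported as a separate scenario.
  current_use_prevalence: 0.072
  # Fraction of current users whose first cigar was flavored.
  flavored_initiation_fraction: 0.654
  # Reduction in initiation among would-be flavored initiates: [min, mode, max].
  initiation_reduction: [0.0, 0.325, 0.65]
  # Adjusted prevalence ratio of current regular use, flavored vs non-flavored
  # initiates; the continuing-reduction mode must equal 1 - 1/ratio.
  continuing_prevalence_ratio: 1.56
  # Reduction in continuing use among non-deterred flavored initiates;
  # min/max derive from the ratio's 95% CI (1.29, 1.87).
  continuing_reduction: [0.225, 0.359, 0.465]
settings:
  n_iterations: 1000
  interval_mass: 0.90
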