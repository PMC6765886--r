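# Cessation-mortality scenario: annual premature deaths avoided among current
# exclusive cigar smokers under a nationwide flavored-cigar prohibition.
model_kind: mortality
inputs:
  # Premature deaths per year among exclusive regular cigar smokers.
  attributable_deaths: 5200
  # Proportional reduction in total cigar consumption: [min, mode, max].
  consumption_reduction: [0.15, 0.30, 0.45]
  # Fraction of the consumption reduction that is complete cessation.
  cessation_fraction: [0.25, 0.50, 0.75]
  # Market-share rationale for the consumption-reduction upper bound:
  # machine-made share of cigars sold x flavored share of retail sales.
  machine_made_share: 0.92
  flavored_retail_share: 0.521
settings:
  n_iterations: 1000
  interval_mass: 0.90
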