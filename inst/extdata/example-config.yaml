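# Example configuration: start from the packaged base-case defaults and
# override a subset of fields. See ?load_parameters for the schema.
use_defaults: true
wtp_per_qaly: 150000
horizon_years: 15
cost_tgt:
  mean: 3500
  ci_low: 2200
  ci_high: 5100
  distribution: gamma
longterm_monthly_death_prob: 0.012
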