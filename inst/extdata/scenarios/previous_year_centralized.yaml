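# Scenario override file: only fields differing from package defaults.
# Omitted fields (cohort, behavior, costs, prevention, discount_rate)
# take the documented defaults.
label: previous_year_centralized
strategy: previous_year
org:
  name: centralized
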