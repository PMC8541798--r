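# Example run configuration. Paths are relative to where the CLI is invoked.
countries: countries.csv
index: market_index.csv
columns:
  iso3: iso3
  name: name
  who_region: who_region
  income_group: income_group
  legal_status: legal_status
  adult_population: adult_population
  prevalence_pct: prevalence_pct
  survey_year: survey_year
survey_year_window: [2012, 2020]
base_year: 2018
z: 1.96
rho: 0.933
min_group_n: 1
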