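{
  "comment": "Illustrative synthetic unit-cost fixture in 2018 SEK. Values are plausible Swedish magnitudes for demonstration and testing; they are not official tariffs.",
  "currency": "SEK",
  "unit_costs": {
    "healthcare_visit_outpatient": 1800,
    "healthcare_visit_primary": 1100,
    "medication": 450,
    "supplement": 150,
    "social_support": 250
  },
  "daily_salary_plus_social_fees": 2480,
  "posttax_hourly_wage": 135,
  "annual_cost_per_pupil": 116000,
  "school_days_per_year": 178,
  "psychologist_hourly_cost": 1100,
  "price_basis": {
    "cpi": { "2018": 330.72, "2022": 363.31 },
    "base_year": 2018,
    "target_year": 2022,
    "ppp_rate": 8.77
  }
}
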