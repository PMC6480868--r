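# Working parameter set of the ward-planning model (EUR, hours, days).
# The loader re-derives every downstream constant from these primitives.
revenue:
  base_case_value: 3117.36      # state base case value, EUR
  cmi_paediatrics: 0.483        # paediatric case-mix index
  obstetric_rebate: 3135.11     # canonical obstetric rebate, EUR/birth
costs:
  variable_paediatrics: 152.59  # EUR/case (drugs, food, ...)
  variable_obstetrics: 244.64   # EUR/birth
  department_fixed_paediatrics: 576500   # EUR/year
  department_fixed_obstetrics: 679000    # EUR/year
  bed_fixed_paediatrics: 15253.47        # EUR/bed/year
  bed_fixed_obstetrics: 20212.24         # EUR/bed/year
  min_beds: 5
  hospital_fixed: 0
paediatrics:
  nursing_hours_per_day: 5.2
  los: 3.1                      # days
  physician_minutes_per_day: 45
obstetrics:
  caesarean_rate: 0.356
  los_vaginal: 3.6
  los_caesarean: 7.3
  nursing_hours_per_day_mother: 2.8
  nursing_hours_per_day_newborn: 1.8
  delivery_duration: 14.5       # midwife hours per birth
  physician_min_vaginal: 60
  physician_min_caesarean: 300
  extra_nursing_caesarean: 300  # theatre nursing, not a ward coefficient
  min_midwives: 5
salaries:
  gross:
    nurse: 42000
    senior_nurse: 50000
    physician: 75000
    senior_physician: 120000
  employer_share: 0.35
  weekly_hours: 40
  absence_weeks: 8
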