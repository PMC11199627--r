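# Default nutrition-guideline policy. Percent-of-energy ranges follow the EFSA
# dietary reference values and the WHO healthy-diet recommendations; they are
# deliberately user-overridable because published guidance is expressed as
# ranges, not point values, and deployments may adopt national variants.
version: 1
energy_rule:
  d_adjust: 500      # kcal added (underweight) or removed (overweight/obese)
  bmi_low: 18.5
  bmi_high: 25
atwater:             # kcal per gram
  protein: 4
  carbohydrate: 4
  fat: 9
  sfa: 9
macro_ranges_pct_energy:
  protein: [10, 20]
  carbohydrate: [45, 60]
  fat: [20, 35]
  sfa: [0, 10]
group_overrides:
  "Adults with CVD":
    sfa: [0, 7]      # stricter saturated-fat cap for cardiovascular disease
  "Adults with T2D":
    carbohydrate: [40, 50]
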