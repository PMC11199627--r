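# Fixed population bounds used to min-max normalize continuous profile fields
# into [0,1] before encoding. Anthropometric bounds are the simulated-cohort
# population ranges; age starts at 15 to cover adolescent profiles.
weight: [46, 180]      # kg
height: [1.60, 2.0]    # m
bmr: [800, 3500]       # kcal/day
age: [15, 88]          # years
bmi: [15, 60]          # kg/m^2
target_ei: [1000, 5000]  # kcal/day
pal: [1.0, 2.5]
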