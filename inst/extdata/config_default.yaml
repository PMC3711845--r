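# Default model configuration: annual MRI + mammography vs annual
# mammography alone for BRCA1/2 mutation carriers.
# All costs in 2008 CAD; probabilities as fractions; ages in years.
meta:
  currency: 2008 CAD
  description: BRCA1/2 breast-cancer screening cost-effectiveness model

model:
  start_age: 25
  horizon_age: 100
  cycle_length_years: 0.5
  discount_rate: 0.035
  mri_ages: [25, 64]            # MRI offered in the combined arm
  mam_ages_combined: [30, 79]   # mammography in the combined arm
  mam_ages_alone: [30, 79]      # annual mammography, comparator arm
  treatment_cycles: 3           # 18 months of treatment after diagnosis
  cure_cycles: 20               # no cancer death >10 years after diagnosis
  terminal_cycles: 3            # progressive disease in last 18 months
  workup_duration_days: 14
  background_mortality:
    gompertz_slope: 0.09        # per-year log-hazard slope, adult female
    target_cum_mortality: 0.209 # all-cause death by target age, comparator arm
    target_age: 65

psa:
  n_draws: 10000
  wtp_grid: [0, 10000, 20000, 30000, 40000, 50000, 60000, 70000, 80000,
             90000, 100000, 120000, 140000, 160000, 180000, 200000]

incidence:
  # 10-year risk of breast cancer by age band (BRCA1/2-weighted)
  bands:
    - {age_lo: 20, age_hi: 30, risk10: 0.015, ci: [0.011, 0.019]}
    - {age_lo: 30, age_hi: 40, risk10: 0.086, ci: [0.069, 0.110]}
    - {age_lo: 40, age_hi: 50, risk10: 0.180, ci: [0.140, 0.230]}
    - {age_lo: 50, age_hi: 60, risk10: 0.200, ci: [0.170, 0.250]}
    - {age_lo: 60, age_hi: 70, risk10: 0.180, ci: [0.150, 0.220]}

screening:
  combined:
    se_combined: {mean: 0.94, ci: [0.90, 0.97]}  # either modality detects
    sp_combined: {mean: 0.77, ci: [0.75, 0.80]}
    se_mri:      {mean: 0.77, ci: [0.70, 0.84]}
    sp_mri:      {mean: 0.86, ci: [0.81, 0.92]}
    se_mam:      {mean: 0.39, ci: [0.37, 0.41]}
    sp_mam:      {mean: 0.95, ci: [0.93, 0.97]}
  mammography_alone:
    # age-specific performance of annual film mammography
    - {age_lo: 30, age_hi: 40,
       se: {mean: 0.63, ci: [0.42, 0.85]}, sp: {mean: 0.894, ci: [0.886, 0.902]}}
    - {age_lo: 40, age_hi: 50,
       se: {mean: 0.70, ci: [0.61, 0.80]}, sp: {mean: 0.867, ci: [0.863, 0.872]}}
    - {age_lo: 50, age_hi: 60,
       se: {mean: 0.81, ci: [0.73, 0.89]}, sp: {mean: 0.873, ci: [0.868, 0.879]}}
    - {age_lo: 60, age_hi: 70,
       se: {mean: 0.84, ci: [0.77, 0.91]}, sp: {mean: 0.890, ci: [0.884, 0.895]}}

stages:
  # stage-at-diagnosis proportions: in_situ, local, regional, distant
  mri_detected:
    p:  [0.16, 0.68, 0.16, 0.01]
    ci: [[0.10, 0.22], [0.62, 0.72], [0.10, 0.22], [0.00, 0.04]]
  mam_detected:
    p:  [0.27, 0.49, 0.22, 0.02]
    ci: [[0.17, 0.38], [0.38, 0.58], [0.12, 0.31], [0.00, 0.11]]
  non_screen:
    p:  [0.05, 0.48, 0.40, 0.08]
    ci: [[0.03, 0.06], [0.46, 0.50], [0.37, 0.42], [0.06, 0.09]]

costs:
  mri:      {mean: 277, ci: [196, 376]}
  mammogram: {mean: 95, ci: [55, 146]}
  workup:   {mean: 187, ci: [106, 292]}
  treatment:  # total over the 18-month treatment window, by stage
    in_situ:  {mean: 3427,  ci: [1713, 5140]}
    local:    {mean: 10940, ci: [1997, 27335]}
    regional: {mean: 23612, ci: [5075, 56124]}
    distant:  {mean: 15645, ci: [4171, 34561]}
  end_of_life: {mean: 26704, ci: [11851, 47489]}  # last 18 months of life

utilities:
  workup: {mean: 0.987, ci: [0.761, 1.00]}  # applies for two weeks
  treatment:
    in_situ:  {mean: 0.965, ci: [0.463, 1.00]}
    local:    {mean: 0.860, ci: [0.330, 1.00]}
    regional: {mean: 0.675, ci: [0.315, 0.929]}
    distant:  {mean: 0.380, ci: [0.211, 0.564]}
  progression: {mean: 0.380, ci: [0.211, 0.564]}
  remission:   {mean: 0.965, ci: [0.463, 1.00]}

survival:
  # 5- and 10-year survival from diagnosis, by stage; in-situ disease does
  # not progress (survival identically 1, no entry needed)
  local:
    s5:  {mean: 0.968, ci: [0.964, 0.971]}
    s10: {mean: 0.906, ci: [0.892, 0.917]}
  regional:
    s5:  {mean: 0.888, ci: [0.847, 0.916]}
    s10: {mean: 0.712, ci: [0.631, 0.769]}
  distant:
    s5:  {mean: 0.261, ci: [0.219, 0.299]}
    s10: {mean: 0.102, ci: [0.072, 0.132]}
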