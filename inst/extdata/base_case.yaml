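schema_version: 1
currency: USD-2017
rate_scale: 100000

economics:
  discount_rate: 0.05
  inflation_rate: 0.047
  wtp: 51000
  cohort_size: 100000
  cycle_length: 1
  horizon_age: 79

# Age-specific schedules, all per 100,000 per year.  Detection rates exist
# only for the screened bands (screening stops at 65-69); the two oldest
# bands are attained-age-only.
age_rates:
  - band: "40-44"
    ec_incidence: 1.36
    ec_incidence_lgin: 4.96
    ec_detection: 16.92
    lgin_detection: 130.56
    ec_mortality: 0.68
    all_cause_mortality: 122.41
  - band: "45-49"
    ec_incidence: 4.90
    ec_incidence_lgin: 17.68
    ec_detection: 70.65
    lgin_detection: 545.00
    ec_mortality: 2.19
    all_cause_mortality: 184.60
  - band: "50-54"
    ec_incidence: 9.93
    ec_incidence_lgin: 34.95
    ec_detection: 193.45
    lgin_detection: 1492.33
    ec_mortality: 7.57
    all_cause_mortality: 343.55
  - band: "55-59"
    ec_incidence: 25.41
    ec_incidence_lgin: 84.00
    ec_detection: 518.59
    lgin_detection: 4000.54
    ec_mortality: 14.87
    all_cause_mortality: 475.18
  - band: "60-64"
    ec_incidence: 35.48
    ec_incidence_lgin: 108.02
    ec_detection: 976.17
    lgin_detection: 7530.48
    ec_mortality: 22.03
    all_cause_mortality: 738.42
  - band: "65-69"
    ec_incidence: 46.25
    ec_incidence_lgin: 118.02
    ec_detection: 2072.48
    lgin_detection: 15987.72
    ec_mortality: 33.08
    all_cause_mortality: 1262.28
  - band: "70-74"
    ec_incidence: 63.97
    ec_incidence_lgin: 163.22
    ec_mortality: 53.42
    all_cause_mortality: 2380.26
  - band: "75-79"
    ec_incidence: 64.45
    ec_incidence_lgin: 164.36
    ec_mortality: 65.73
    all_cause_mortality: 4094.67

# Stage distribution of esophageal cancer at diagnosis (proportions).
stage_distribution:
  nonscreening:
    ic: 0.0365
    sm: 0.0493
    mod: 0.6606
    adv: 0.2536
  screening:
    ic: 0.8824
    sm: 0.0252
    mod: 0.0672
    adv: 0.0252
  sa_range:
    nonscreening:
      ic: [0.0292, 0.0438]
      sm: [0.0394, 0.0592]
      mod: [0.5285, 0.7927]
      adv: [0.2029, 0.3043]
    screening:
      ic: [0.7059, 1.0000]
      sm: [0.0202, 0.0302]
      mod: [0.0538, 0.0806]
      adv: [0.0202, 0.0302]
  distribution: dirichlet

# State-specific costs, USD-2017.  Screening costs are the one-time
# endoscopy cost; treatment costs accrue per year spent in the state.
costs:
  screening:
    NORMAL: 60.3
    LGIN: 60.3
    IC: 60.3
    SM: 60.3
    MOD: 60.3
    ADV: 60.3
    DFS_IC: 0.0
    DFS_SM: 0.0
    DFS_MOD: 0.0
    PFS_ADV: 0.0
    DEATH: 0.0
  treatment:
    NORMAL: 0.0
    LGIN: 149.5
    IC: 17561.9
    SM: 20781.6
    MOD: 25217.4
    ADV: 23702.5
    DFS_IC: 837.5
    DFS_SM: 1580.0
    DFS_MOD: 1580.0
    PFS_ADV: 2873.0
    DEATH: 0.0
  sa_fraction: 0.30
  distribution: gamma

# State utilities (QALY weight per year) with SD and one-way SA range.
utilities:
  NORMAL:  {mean: 1.000, sd: 0.000, sa_range: [0.000, 0.000]}
  LGIN:    {mean: 0.941, sd: 0.089, sa_range: [0.753, 1.000]}
  IC:      {mean: 0.852, sd: 0.029, sa_range: [0.682, 1.000]}
  DFS_IC:  {mean: 0.940, sd: 0.100, sa_range: [0.752, 1.000]}
  SM:      {mean: 0.693, sd: 0.310, sa_range: [0.554, 0.832]}
  DFS_SM:  {mean: 0.870, sd: 0.150, sa_range: [0.696, 1.000]}
  MOD:     {mean: 0.780, sd: 0.140, sa_range: [0.624, 0.936]}
  DFS_MOD: {mean: 0.810, sd: 0.170, sa_range: [0.648, 0.972]}
  ADV:     {mean: 0.720, sd: 0.180, sa_range: [0.576, 0.864]}
  PFS_ADV: {mean: 0.740, sd: 0.190, sa_range: [0.592, 0.888]}
  DEATH:   {mean: 0.000, sd: 0.000, sa_range: [0.000, 0.000]}
  distribution: beta

# Annual transition scalars.  "gross" values are the published figures from
# which the background death probability d_nor is subtracted when a row is
# composed; splits are stage simplexes over destination cancer states.
scalars:
  lgin_to_normal:    {value: 0.1427, sa_range: [0.1142, 0.1712], dist: beta}
  ic_to_dfs_gross:   {value: 0.9363, sa_range: [0.7490, 0.9363], dist: beta}
  ic_progress:       {value: 0.0534, sa_range: [0.0427, 0.0641], dist: beta}
  ic_progress_split:
    sm:  {value: 0.2143, sa_range: [0.1714, 0.2572]}
    mod: {value: 0.5714, sa_range: [0.4571, 0.6857]}
    adv: {value: 0.2143, sa_range: [0.1714, 0.2572]}
    dist: dirichlet
  dfs_ic_to_ic:      {value: 0.0069, sa_range: [0.0055, 0.0083], dist: beta}
  dfs_ic_progress:   {value: 0.0268, sa_range: [0.0214, 0.0322], dist: beta}
  dfs_ic_progress_split:
    sm:  {value: 0.5556, sa_range: [0.4445, 0.6667]}
    mod: {value: 0.4444, sa_range: [0.3555, 0.5333]}
    adv: {value: 0.0000, sa_range: [0.0000, 0.0000]}
    dist: dirichlet
  sm_to_dfs_gross:   {value: 0.9051, sa_range: [0.7241, 1.0000], dist: beta}
  sm_progress:       {value: 0.1386, sa_range: [0.1109, 0.1663], dist: beta}
  sm_progress_split:
    mod: {value: 0.7562, sa_range: [0.6050, 0.9074]}
    adv: {value: 0.2438, sa_range: [0.1950, 0.2926]}
    dist: beta
  dfs_sm_to_sm:      {value: 0.0393, sa_range: [0.0314, 0.0472], dist: beta}
  dfs_sm_progress:   {value: 0.0883, sa_range: [0.0706, 0.1060], dist: beta}
  mod_to_dfs_gross:  {value: 0.5930, sa_range: [0.4744, 0.7116], dist: beta}
  mod_to_adv:        {value: 0.0317, sa_range: [0.0254, 0.0380], dist: beta}
  dfs_mod_to_mod:    {value: 0.0425, sa_range: [0.0340, 0.0510], dist: dirichlet}
  dfs_mod_to_adv:    {value: 0.0097, sa_range: [0.0078, 0.0116], dist: dirichlet}
  adv_to_pfs_gross:  {value: 0.1967, sa_range: [0.1574, 0.2360], dist: dirichlet}
  pfs_progress:      {value: 0.7002, sa_range: [0.5602, 0.8402], dist: dirichlet}
  rr_screening:      {value: 0.7000, sa_range: [0.5600, 0.8400], dist: lognormal}
  lgin_ec_risk_ratio: {value: 3.66}
  ec_death:
    sm:      {value: 0.0994, sa_range: [0.0795, 0.1193], dist: beta}
    dfs_sm:  {value: 0.0633, sa_range: [0.0506, 0.0760], dist: beta}
    mod:     {value: 0.2988, sa_range: [0.2390, 0.3586], dist: beta}
    dfs_mod: {value: 0.1902, sa_range: [0.1522, 0.2282], dist: beta}
    adv:     {value: 0.4613, sa_range: [0.3690, 0.5536], dist: beta}
    pfs:     {value: 0.4303, sa_range: [0.3442, 0.5164], dist: beta}
  elderly_death_rr:
    sm:  {value: 1.30, sa_range: [1.20, 1.50], dist: lognormal}
    mod: {value: 1.20, sa_range: [1.10, 1.30], dist: lognormal}
    adv: {value: 1.16, sa_range: [1.10, 1.20], dist: lognormal}
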