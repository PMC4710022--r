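# Default simulation scenario: two competing causes, all-cause hazard 0.1
# split equally (true F1(t) = 0.5 * (1 - exp(-0.1 t))), uniform censoring on
# (0.5, 10.5) (~15% censored by t = 2), administrative censoring at t = 2,
# case-control phase-II sampling of 50 cases + 50 controls from N = 1000.
design_kind: case_control
n_phase2: 100
n_cohort: 1000
total_hazard: 0.1
cause_split: 0.5
censor_low: 0.5
censor_high: 10.5
admin_horizon: 2
B: 100
alpha: 0.05
seed: 1
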