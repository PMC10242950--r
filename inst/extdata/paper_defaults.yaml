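# Default pipeline configuration: three-group adolescent cohort with the
# published post-exclusion group sizes and round-level calibration targets.
# All values are published group statistics except where marked synthetic.
seed: 7
task:
  true_counts: [43, 58, 34, 44, 39]   # fixed stimulus schedule
  delta_band: [0.15, 0.25]            # relative offset band for X around E1
  sign_schedule: [1, -1, 1, -1, 1]    # balanced up/down offsets
  min_distance: 2                     # so a compromise is representable
groups:
  TD:
    n_participants: 45
    p_comp: 0.6411            # compromise share of valid rounds
    mean_s: 0.36              # mean adjustment weight
    prop_s_below_half: 0.80   # share of rounds with s < 0.5
    tau00: 3.96               # between-participant logit-scale variance
    accuracy_mean: 0.69       # mean E1 as fraction of the true count
    accuracy_cv: 0.25
    age_mean: 14.13
    age_sd: 1.26
    iq_mean: 90.4
    iq_sd: 11.40
  CP_LCU:
    n_participants: 31
    p_comp: 0.3586
    mean_s: 0.32
    prop_s_below_half: 0.7419
    tau00: 3.96
    accuracy_mean: 0.68
    accuracy_cv: 0.25
    age_mean: 13.56
    age_sd: 1.38
    iq_mean: 87.53
    iq_sd: 10.30
  CP_HCU:
    n_participants: 32
    p_comp: 0.50              # synthetic: not published, interpolated
    mean_s: 0.36
    prop_s_below_half: 0.6875
    tau00: 3.96
    accuracy_mean: 0.74
    accuracy_cv: 0.25
    age_mean: 14.56
    age_sd: 1.22
    iq_mean: 84.85
    iq_sd: 8.85
codings: [aon_vs_comp, stay_vs_rest, copy_vs_rest]
covariate_sets:
  - []
  - [age, iq]
n_replicates: 1
invalid_rate: 0.0
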