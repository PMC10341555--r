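# Canonical 79-feature schema: number, key, block, axis.
# Durations in seconds; cadence in steps/min; step length in m;
# gait speed in m/s; CVs in percent; other features in signal units.
features:
  - number: 1
    name: mse_mean_tug_ML
    block: tug
    axis: ML
  - number: 2
    name: mse_mean_tug_V
    block: tug
    axis: V
  - number: 3
    name: mse_mean_tug_AP
    block: tug
    axis: AP
  - number: 4
    name: mse_sd_tug_ML
    block: tug
    axis: ML
  - number: 5
    name: mse_sd_tug_V
    block: tug
    axis: V
  - number: 6
    name: mse_sd_tug_AP
    block: tug
    axis: AP
  - number: 7
    name: mse_ci_tug_ML
    block: tug
    axis: ML
  - number: 8
    name: mse_ci_tug_V
    block: tug
    axis: V
  - number: 9
    name: mse_ci_tug_AP
    block: tug
    axis: AP
  - number: 10
    name: pe_tug_ML
    block: tug
    axis: ML
  - number: 11
    name: pe_tug_V
    block: tug
    axis: V
  - number: 12
    name: pe_tug_AP
    block: tug
    axis: AP
  - number: 13
    name: stand_duration
    block: sist
  - number: 14
    name: range_sist_ML
    block: sist
    axis: ML
  - number: 15
    name: range_sist_V
    block: sist
    axis: V
  - number: 16
    name: range_sist_AP
    block: sist
    axis: AP
  - number: 17
    name: max_sist_ML
    block: sist
    axis: ML
  - number: 18
    name: max_sist_V
    block: sist
    axis: V
  - number: 19
    name: max_sist_AP
    block: sist
    axis: AP
  - number: 20
    name: rms_sist_ML
    block: sist
    axis: ML
  - number: 21
    name: rms_sist_V
    block: sist
    axis: V
  - number: 22
    name: rms_sist_AP
    block: sist
    axis: AP
  - number: 23
    name: max_jerk_sist_ML
    block: sist
    axis: ML
  - number: 24
    name: max_jerk_sist_V
    block: sist
    axis: V
  - number: 25
    name: max_jerk_sist_AP
    block: sist
    axis: AP
  - number: 26
    name: min_sist_ML
    block: sist
    axis: ML
  - number: 27
    name: min_sist_V
    block: sist
    axis: V
  - number: 28
    name: min_sist_AP
    block: sist
    axis: AP
  - number: 29
    name: mean_jerk_sist_ML
    block: sist
    axis: ML
  - number: 30
    name: mean_jerk_sist_V
    block: sist
    axis: V
  - number: 31
    name: mean_jerk_sist_AP
    block: sist
    axis: AP
  - number: 32
    name: sd_sist_ML
    block: sist
    axis: ML
  - number: 33
    name: sd_sist_V
    block: sist
    axis: V
  - number: 34
    name: sd_sist_AP
    block: sist
    axis: AP
  - number: 35
    name: walk_duration
    block: walk
  - number: 36
    name: cadence
    block: walk
  - number: 37
    name: step_length
    block: walk
  - number: 38
    name: gait_speed
    block: walk
  - number: 39
    name: step_time
    block: walk
  - number: 40
    name: stride_time
    block: walk
  - number: 41
    name: cv_step_time
    block: walk
  - number: 42
    name: cv_stride_time
    block: walk
  - number: 43
    name: rms_walk_ML
    block: walk
    axis: ML
  - number: 44
    name: rms_walk_V
    block: walk
    axis: V
  - number: 45
    name: rms_walk_AP
    block: walk
    axis: AP
  - number: 46
    name: cv_turn_ML
    block: turn
    axis: ML
  - number: 47
    name: cv_turn_V
    block: turn
    axis: V
  - number: 48
    name: cv_turn_AP
    block: turn
    axis: AP
  - number: 49
    name: median_turn_ML
    block: turn
    axis: ML
  - number: 50
    name: median_turn_V
    block: turn
    axis: V
  - number: 51
    name: median_turn_AP
    block: turn
    axis: AP
  - number: 52
    name: range_turn_ML
    block: turn
    axis: ML
  - number: 53
    name: range_turn_V
    block: turn
    axis: V
  - number: 54
    name: range_turn_AP
    block: turn
    axis: AP
  - number: 55
    name: rms_turn_ML
    block: turn
    axis: ML
  - number: 56
    name: rms_turn_V
    block: turn
    axis: V
  - number: 57
    name: rms_turn_AP
    block: turn
    axis: AP
  - number: 58
    name: sit_duration
    block: stsi
  - number: 59
    name: range_stsi_ML
    block: stsi
    axis: ML
  - number: 60
    name: range_stsi_V
    block: stsi
    axis: V
  - number: 61
    name: range_stsi_AP
    block: stsi
    axis: AP
  - number: 62
    name: rms_stsi_ML
    block: stsi
    axis: ML
  - number: 63
    name: rms_stsi_V
    block: stsi
    axis: V
  - number: 64
    name: rms_stsi_AP
    block: stsi
    axis: AP
  - number: 65
    name: min_stsi_ML
    block: stsi
    axis: ML
  - number: 66
    name: min_stsi_V
    block: stsi
    axis: V
  - number: 67
    name: min_stsi_AP
    block: stsi
    axis: AP
  - number: 68
    name: max_stsi_ML
    block: stsi
    axis: ML
  - number: 69
    name: max_stsi_V
    block: stsi
    axis: V
  - number: 70
    name: max_stsi_AP
    block: stsi
    axis: AP
  - number: 71
    name: max_jerk_stsi_ML
    block: stsi
    axis: ML
  - number: 72
    name: max_jerk_stsi_V
    block: stsi
    axis: V
  - number: 73
    name: max_jerk_stsi_AP
    block: stsi
    axis: AP
  - number: 74
    name: mean_jerk_stsi_ML
    block: stsi
    axis: ML
  - number: 75
    name: mean_jerk_stsi_V
    block: stsi
    axis: V
  - number: 76
    name: mean_jerk_stsi_AP
    block: stsi
    axis: AP
  - number: 77
    name: sd_stsi_ML
    block: stsi
    axis: ML
  - number: 78
    name: sd_stsi_V
    block: stsi
    axis: V
  - number: 79
    name: sd_stsi_AP
    block: stsi
    axis: AP
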