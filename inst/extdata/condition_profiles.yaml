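# Condition profiles, version 1.
#
# Each number is annotated with the in-vivo quantity it encodes (reported
# group summary statistics from the zebrafish sensory-neuron aSyn model) or
# marked "assumed" where the condition was never measured for that quantity.
# Dispersion parameters were derived once from printed mean +/- s.e.m. and n
# (sd = s.e.m. * sqrt(n)); dwell times follow from the paused-time target f
# via mean_pause = mean_run * f / (1 - f) under the stationary renewal model.
version: 1
conditions:
  - name: WT
    transport:
      motile_fraction: 0.274              # measured % motile 27.4 +/- 2.7
      anterograde_run_speed_mean: 0.56    # um/s, measured 0.56 +/- 0.04 (sem)
      anterograde_run_speed_sd: 0.15      # between-run spread (capped, see docs)
      retrograde_run_speed_mean: 0.57     # um/s, measured 0.57 +/- 0.04 (sem)
      retrograde_run_speed_sd: 0.15
      mean_run_duration: 6                # s, assumed (typical in vivo run)
      mean_pause_duration: 4.213          # s, = 6 * 0.4125 / 0.5875
      prob_next_run_retrograde: 0.3797    # = retro time 22.31 / moving time 58.75
      target_time_fraction_paused: 0.4125 # measured % time paused 41.25 +/- 4.43
    morphology:
      density_per_100um: 22.6             # printed magnitude /10 (unit ambiguity)
      aspect_ratio_mean: 2.01             # measured length:width 2.01 +/- 0.11
      aspect_ratio_sd: 0.81               # 0.11 * sqrt(54)
      mito_minor_axis_um: 0.7             # assumed axonal mito diameter
      swollen_fraction: 0.05              # near-spherical minority in WT
    axonopathy:
      stage_probabilities_at_2dpf: [0.9167, 0.0833, 0, 0, 0]   # 11/12, 1/12
      stage_transition_matrix_per_day:    # fit to 2->3 dpf counts 11,1 -> 10,1,0,0,1
        - [0.9091, 0, 0, 0, 0.0909]
        - [0, 1, 0, 0, 0]
        - [0, 0, 1, 0, 0]
        - [0, 0, 0, 0.5, 0.5]
        - [0, 0, 0, 0, 1]
      death_given_stage5: 1.0             # the observed WT stage 5 was a cell death
    timing:
      lag_mean: 129.1                     # min, measured 129.1 +/- 10.0 (sem, n=11)
      lag_sd: 33.2                        # 10.0 * sqrt(11)
      clearance_mean: 58.2                # min, measured 58.2 +/- 6.9 (sem)
      clearance_sd: 22.9                  # 6.9 * sqrt(11)
      axonopathy_onset_lead_hours: 4      # swellings precede death by several hours
      sampling_interval: 30               # min between frames post-transection
    survival_2to3dpf: 1.0                 # no WT deaths; mean survival 102.9 +/- 3.2 %
    new_expression_rate: 0.029            # new reporter-positive cells -> >100 %
  - name: aSyn
    transport:
      motile_fraction: 0.1505             # measured % motile 15.05 +/- 3.4
      anterograde_run_speed_mean: 0.53    # um/s, measured 0.53 +/- 0.06 (sem)
      anterograde_run_speed_sd: 0.15
      retrograde_run_speed_mean: 0.64     # um/s, measured 0.64 +/- 0.07 (sem)
      retrograde_run_speed_sd: 0.15
      mean_run_duration: 6
      mean_pause_duration: 7.281          # = 6 * 0.5482 / 0.4518
      prob_next_run_retrograde: 0.6151    # = retro time 27.79 / moving time 45.18
      target_time_fraction_paused: 0.5482 # measured % time paused 54.82 +/- 4.85
    morphology:
      density_per_100um: 30.2             # higher density than WT (directional)
      aspect_ratio_mean: 1.48             # measured 1.48 +/- 0.05
      aspect_ratio_sd: 0.37               # 0.05 * sqrt(54)
      mito_minor_axis_um: 0.7
      swollen_fraction: 0.25              # more spherical mitochondria than WT
    axonopathy:
      stage_probabilities_at_2dpf: [0.1579, 0.6316, 0.2105, 0, 0]  # 3,12,4 of 19
      stage_transition_matrix_per_day:    # fit to 2->3 dpf counts 3,12,4 -> 2,8,2,1,6
        - [0.6667, 0.3333, 0, 0, 0]
        - [0, 0.5834, 0.0833, 0, 0.3333]
        - [0, 0, 0.25, 0.25, 0.5]
        - [0, 0, 0, 0.5, 0.5]
        - [0, 0, 0, 0, 1]
      death_given_stage5: 1.0             # dying cells fully degenerate
    timing:
      lag_mean: 112.7                     # min, measured 112.7 +/- 11.7 (sem, n=15)
      lag_sd: 45.3                        # 11.7 * sqrt(15)
      clearance_mean: 69.1                # min, measured 69.1 +/- 8.3 (sem)
      clearance_sd: 32.1                  # 8.3 * sqrt(15)
      axonopathy_onset_lead_hours: 4      # stage 2-3 precedes death by several hours
      sampling_interval: 30
    survival_2to3dpf: 0.817               # measured survival 81.7 +/- 4.4 %
    new_expression_rate: 0.0
  - name: aSyn+WldS
    transport:                            # assumed: aSyn-like (not measured)
      motile_fraction: 0.1505
      anterograde_run_speed_mean: 0.53
      anterograde_run_speed_sd: 0.15
      retrograde_run_speed_mean: 0.64
      retrograde_run_speed_sd: 0.15
      mean_run_duration: 6
      mean_pause_duration: 7.281
      prob_next_run_retrograde: 0.6151
      target_time_fraction_paused: 0.5482
    morphology:                           # assumed: aSyn-like (not measured)
      density_per_100um: 30.2
      aspect_ratio_mean: 1.48
      aspect_ratio_sd: 0.37
      mito_minor_axis_um: 0.7
      swollen_fraction: 0.25
    axonopathy:
      stage_probabilities_at_2dpf: [0.55, 0.36, 0.06, 0.03, 0]  # mean 1.57 +/- 0.11
      stage_transition_matrix_per_day:    # coarse fit: 25.7 % reach stage 5 by 3 dpf
        - [0.6, 0.2, 0, 0, 0.2]
        - [0, 0.5, 0.2, 0.05, 0.25]
        - [0, 0, 0.4, 0.3, 0.3]
        - [0, 0, 0, 0.5, 0.5]
        - [0, 0, 0, 0, 1]
      death_given_stage5: 1.0
    timing:
      lag_mean: 600                       # min, assumed: WldS delays fragmentation
      lag_sd: 100
      clearance_mean: 120                 # min, assumed
      clearance_sd: 40
      axonopathy_onset_lead_hours: 6
      sampling_interval: 30
    survival_2to3dpf: 0.869               # measured survival 86.86 +/- 4.43 %
    new_expression_rate: 0.0
  - name: aSyn+PGC1a
    transport:                            # assumed: WT-like (protected)
      motile_fraction: 0.274
      anterograde_run_speed_mean: 0.56
      anterograde_run_speed_sd: 0.15
      retrograde_run_speed_mean: 0.57
      retrograde_run_speed_sd: 0.15
      mean_run_duration: 6
      mean_pause_duration: 4.213
      prob_next_run_retrograde: 0.3797
      target_time_fraction_paused: 0.4125
    morphology:                           # assumed: WT-like (protected)
      density_per_100um: 22.6
      aspect_ratio_mean: 2.01
      aspect_ratio_sd: 0.81
      mito_minor_axis_um: 0.7
      swollen_fraction: 0.05
    axonopathy:
      stage_probabilities_at_2dpf: [0.9333, 0.0667, 0, 0, 0]  # mean 1.07 +/- 0.07
      stage_transition_matrix_per_day:    # near-identity: protection persists to 3 dpf
        - [0.95, 0.04, 0, 0, 0.01]
        - [0, 0.9, 0.08, 0, 0.02]
        - [0, 0, 0.8, 0.1, 0.1]
        - [0, 0, 0, 0.5, 0.5]
        - [0, 0, 0, 0, 1]
      death_given_stage5: 1.0
    timing:                               # assumed: WT-like
      lag_mean: 129.1
      lag_sd: 33.2
      clearance_mean: 58.2
      clearance_sd: 22.9
      axonopathy_onset_lead_hours: 4
      sampling_interval: 30
    survival_2to3dpf: 0.986               # measured survival 98.61 +/- 0.95 %
    new_expression_rate: 0.0
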