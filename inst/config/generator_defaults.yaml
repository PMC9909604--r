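# Default subject-parameter distributions for synthetic cohort generation.
# These encode the standard validation protocol: free rhythmic arm
# exercises paced by a metronome at 15 movements/min (exercises 1-3) and a
# low-workload hand ergometer at 40-45 rpm (exercise 4), performed in a
# metabolic chamber with ~5 kJ/min resting energy expenditure.
rhythmic:
  movement_rate: 15            # metronome beats per minute
  burst_width_range: [0.8, 1.6]   # seconds; movement speed is left free
  burst_amplitude_meanlog: 2.4849  # lognormal, median 12 m/s^2 peak
  burst_amplitude_sdlog: 0.25
  amplitude_jitter: 0.3        # lognormal sd of per-burst amplitude
  noise_sd_range: [0.2, 0.5]   # per-axis sensor noise, m/s^2
  rotation_amplitude_meanlog: 2.3026  # lognormal, median 10 rad/s peak
  rotation_amplitude_sdlog: 0.3
  rotation_noise_sd: 0.15      # rad/s
ergometer:
  cadence_range_rpm: [40, 45]
  amplitude_mean: 3.2          # mean acceleration magnitude, m/s^2
  amplitude_sd: 0.4
  amplitude_jitter: 0.1        # relative per-sample jitter
  noise_sd: 0.02
  rotation_amplitude_mean: 1.2 # rad/s
  rotation_amplitude_sd: 0.3
  rotation_noise_sd: 0.02
chamber:
  resting_ee_mean: 5.0         # kJ/min
  resting_ee_sd: 0.7
anthropometrics:
  age_range: [20, 55]          # years
  height_mean: 171             # cm
  height_sd: 10.5
  weight_mean: 72              # kg
  weight_sd: 12
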