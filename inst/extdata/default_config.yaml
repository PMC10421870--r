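# Default gazelapse pipeline configuration.
# Every fixed constant of the pipeline appears exactly once below.

seed: 1

simulate:
  n_recordings: 22        # cohort size of a typical simulator study
  duration: 5400          # 90-minute session, seconds
  scanpath:
    sample_rate: 100      # eye-tracker sampling frequency, Hz
    blink_rate: 15        # blinks per minute
    pupil_baseline: 4.0   # mm
  episodes:
    episode_rate: 6                     # forgetting episodes per hour
    episode_duration_range: [30, 90]    # seconds
    fixation_duration_multiplier: 1.5
    saccade_amplitude_multiplier: 0.7
    blink_rate_multiplier: 1.5
    pupil_shift_mm: 0.3

events:
  dispersion_threshold: 30      # px, I-DT spread bound
  min_fixation_duration: 0.1    # s
  min_blink_duration: 0.05      # s
  max_blink_duration: 0.5       # s

model:
  seq_len: 6          # events per sequence
  tc_width: 23        # time-related features
  tic_width: 21       # time-independent features
  channels: 64        # convolution kernels per layer
  conv_layers: 3
  hidden: 128         # LSTM units per layer
  lstm_layers: 3

training:
  learning_rate: 0.0001
  epochs: 100
  batch_size: 64
  folds: 5
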