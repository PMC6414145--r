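# Demo study configuration: wedged 14 x 8 cm^2 treatment field through a
# 16 cm breast phantom; sinusoidal motion grid (amplitudes 0.5/1.0/1.5 cm
# at 12/15/20 cycles/min, plus 1.5 cm at 18 cycles/min) and two
# patient-like irregular breathing traces.
phantom:
  separation_max: 16
beam:
  field_size_x: 14
  field_size_y: 8
  wedge: true
calibration:
  thicknesses: [0, 2, 4, 7, 11, 16, 21]
scatter:
  k0: 1.93e-5
acquisition:
  n_frames: 60
  frame_time: 0.43
  pixels_x: 256
  pixels_y: 256
  pixel_pitch: 0.1
  noise_scale: 0.005
  dark_level: 100
motion_set:
  - {kind: sinusoid, amplitude: 0.5, frequency: 12}
  - {kind: sinusoid, amplitude: 0.5, frequency: 15}
  - {kind: sinusoid, amplitude: 0.5, frequency: 20}
  - {kind: sinusoid, amplitude: 1.0, frequency: 12}
  - {kind: sinusoid, amplitude: 1.0, frequency: 15}
  - {kind: sinusoid, amplitude: 1.0, frequency: 20}
  - {kind: sinusoid, amplitude: 1.5, frequency: 12}
  - {kind: sinusoid, amplitude: 1.5, frequency: 15}
  - {kind: sinusoid, amplitude: 1.5, frequency: 20}
  - {kind: sinusoid, amplitude: 1.5, frequency: 18}
  - {kind: patient, mean_period: 4.0, period_cv: 0.15, mean_amplitude: 1.0,
     amplitude_cv: 0.2, baseline_drift: 0}
  - {kind: patient, mean_period: 3.5, period_cv: 0.25, mean_amplitude: 1.3,
     amplitude_cv: 0.3, baseline_drift: 0.15}
analysis:
  criteria: [[5, 5], [3, 3], [2, 2], [1, 1]]
  thresholds: [5, 3, 2, 1]
  field_threshold: 0.1
  roi: auto
seed: 1
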