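# scripted maneuver: stand upright, lean forward, hold, straighten
segments:
  - duration: 5
    target_pitch: 0
    target_roll: 0
    transition: hold
  - duration: 3
    target_pitch: 30
    target_roll: 0
    transition: linear
  - duration: 10
    target_pitch: 30
    target_roll: 0
    transition: hold
  - duration: 3
    target_pitch: 0
    target_roll: 0
    transition: linear
  - duration: 5
    target_pitch: 0
    target_roll: 0
    transition: hold
sample_rate: 10
noise_sigma: 0.005
seed: 1
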