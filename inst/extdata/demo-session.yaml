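# Demo motion script: a 14 s synthetic session at 60 Hz with three left
# reaches after the 10 s buffer and a short grooming bout.
duration: 14
frame_rate: 60
drop_probability: 0.1
baseline_jitter_sd: 0.5
timestamp_jitter_sd: 4.16
seed: 3
reach_events:
  - onset: 11.0
    paw: left
    amplitude: 20
    rise: 0.1
  - onset: 12.0
    paw: left
    amplitude: 25
    rise: 0.1
  - onset: 13.0
    paw: left
    amplitude: 20
    rise: 0.1
grooming_intervals:
  - start: 4.0
    end: 5.5
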