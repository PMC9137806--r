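# Small demonstration delivery: motorway approach, cobblestone village
# crossing, and a rough farm access road. Coordinates are synthetic.
segments:
  - surface: A
    speed: 120
    target_dbar: 0.74
    between_trial_sd: 0.05
    duration_s: 120
    start: [52.1000, 9.5000]
    end: [52.1300, 9.5600]
  - surface: C
    speed: 30
    target_dbar: 3.60
    between_trial_sd: 0.18
    duration_s: 60
    start: [52.1300, 9.5600]
    end: [52.1330, 9.5650]
  - surface: D
    speed: 30
    target_dbar: 2.14
    between_trial_sd: 0.21
    impulse_rate: 6
    impulse_scale: 5
    duration_s: 90
    start: [52.1330, 9.5650]
    end: [52.1360, 9.5700]
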