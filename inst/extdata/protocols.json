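{
  "comment": "Default voltage-clamp protocol grids. Reconstructions chosen to satisfy the documented sweep counts (6/7/16/9), summary-curve cardinalities (7/8/9/17/9) and total durations (Pr2-5: 228 s, Pr7: 8 s); replace with archived protocol files for exact replication of published experiments.",
  "dt": 0.1,
  "mask_ms": 5,
  "holding": -80,
  "Pr2": {
    "hold1": 1000,
    "p1_voltage": 40,
    "p1_durations": [100, 300, 800, 2000, 4800, 7000],
    "tail_voltage": -120,
    "tail": 500,
    "hold2": 3500
  },
  "Pr3": {
    "hold1": 1000,
    "p1_voltages": [-60, -40, -20, 0, 20, 40, 60],
    "p1_duration": 5000,
    "tail_voltage": -120,
    "tail": 500,
    "hold2": 3500
  },
  "Pr4": {
    "hold1": 500,
    "p1_voltage": 40,
    "p1": 1000,
    "p2_voltage": -120,
    "p2": 8,
    "p3_voltages": [-110, -100, -90, -80, -70, -60, -50, -40, -30, -20, -10, 0, 10, 20, 30, 40],
    "p3": 120,
    "hold2": 372
  },
  "Pr5": {
    "hold1": 1000,
    "p1_voltage": 40,
    "p1": 2000,
    "p2_voltages": [-120, -110, -100, -90, -80, -70, -60, -50, 40],
    "p2": 5000,
    "hold2": 1000
  },
  "Pr7": {
    "hold1": 1000,
    "step_voltage": 40,
    "step": 1000,
    "sine_offset": -30,
    "sine_amplitudes": [54, 26, 10],
    "sine_omegas": [0.007, 0.037, 0.19],
    "sine_phases": [0, 0, 0],
    "sine_duration": 5500,
    "hold2": 500
  }
}
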