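# Brief localized pulse on a reduced (level-3) ternary grid: the
# reference pulse experiment scaled down for quick exploration.
name: sim1_pulse
l: 3
time:
  t_end: 20
  dt: 0.05
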