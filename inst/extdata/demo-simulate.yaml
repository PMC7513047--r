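# example configuration for `activeblend simulate`
system:
  M: 16
  N: 40
  density: 0.85
  box_aspect: [1, 1, 2]
thermostats:
  Tc: 1.0
  Th: 3.0
  zeta: 1.5
run:
  dt: 0.005
  duration: 100
  sample_interval: 10
  seed: 1
output:
  trajectory: trajectory.txt
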