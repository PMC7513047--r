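# example configuration for `activeblend fixtures`
box: [16, 16, 32]
rho_hot_phase: 0.75
rho_cold_phase: 0.95
T_hot: 2.6
T_cold: 1.2
n_frames: 12
seed: 1
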