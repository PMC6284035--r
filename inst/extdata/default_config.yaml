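variant: NH3
t_end: 79.0
dt_out: 0.1
rtol: 1.0e-08
atol: 1.0e-12
seed: 1
log_level: info
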