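condition: mixed_uniform_n500
distribution: uniform
gs_setting: mixed
'n': 500
replications: 30
base_seed: 1
methods:
- IRP_EM
- IRP_GD
- GDINA
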