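condition: flat_uniform_n1000
distribution: uniform
gs_setting: flat
'n': 1000
replications: 30
base_seed: 1
methods:
- IRP_EM
- IRP_GD
- GDINA
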