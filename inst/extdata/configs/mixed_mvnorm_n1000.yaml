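condition: mixed_mvnorm_n1000
distribution: mvnorm
gs_setting: mixed
'n': 1000
replications: 30
base_seed: 1
methods:
- IRP_EM
- IRP_GD
- GDINA
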