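seed: 1
noise_cv: 0.03
n_per_dose: 10
species:
- common_carp
- danube_sturgeon
- rainbow_trout
it_max_s: 180
rt_max_s: 300
output_dir: results
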