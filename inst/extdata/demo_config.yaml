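# demo pipeline configuration: simulated library + slab, all stages
seed: 1
simulate: true
hdr_level: 0.95
alpha: 0.05
dataset_id: 1
grid_nx: 151
grid_ny: 151
permutations: 999
shrinkage_d: 0.20
min_measurements: 5
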