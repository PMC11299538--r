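# Full-scale primary synthetic evaluation grid (540 cells x 100 trains).
# Reduce `reps` for desk-scale runs.
T: [30720, 61440, 122880]
f_osc: [7, 9, 12, 20, 32]
p_base_offset: [1, 2, 4, 8, 16, 32]
m: [0.0, 0.2, 0.4, 0.6, 0.8, 1.0]
n_r: 9
k: 0.7
reps: 100
seed: 1
n_surrogates: 100
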