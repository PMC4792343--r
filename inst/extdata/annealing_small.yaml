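# Example run configuration: small annealing aggregate.
scenario: annealing
n_cells: 12
seed: 4
n_steps: 400
snapshot_stride: 100
mode: polyline
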