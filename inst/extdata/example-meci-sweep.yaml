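# Example run configuration: MECI search with an alpha sweep (three repeats
# per alpha), on the 2-D benchmark with noisy energies.
target: MECI
oracle: benchmark_2d
alpha: [1, 10, 25, 50, 75, 100]
campaigns: 3
seed: 1
noise_half_width: 2.0
acquisition:
  kind: PI
init:
  mode: uniform
  n_structures: 20
bo:
  n_random: 400
  n_select: 20
  max_iterations: 200
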