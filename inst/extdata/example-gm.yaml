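# Example run configuration: three-repeat GM search on the 2-D benchmark.
# Usage: exec/bogeom run --config example-gm.yaml --seed 1 --out results/
target: GM
oracle: benchmark_2d
campaigns: 3
seed: 1
noise_half_width: 0.0
init:
  mode: uniform
  n_structures: 20
bo:
  n_random: 400
  n_select: 20
  max_iterations: 200
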