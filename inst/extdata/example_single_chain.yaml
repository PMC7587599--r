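# Example run configuration: one fully flexible 20-bead IDR sampled in
# near-isolation at T* = 1.9872 (all quantities in reduced units).
# Run with:  llpsmd run --config example_single_chain.yaml --out coil
protocol: single_chain
seed: 1
protein:
  n_beads: 20
  k_theta: 0        # 0 = random coil ... 20 = fully extended
  species: A
integrator:
  n_steps: 1000000
  T_target: 1.9872
  thermostat: langevin
  thermo_every: 10000
  snapshot_every: 1000
output:
  prefix: coil
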