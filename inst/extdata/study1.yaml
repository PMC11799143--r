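# Full-scale condition sweep for the adjustment-model simulation:
# two stimulus difficulties, SAT (max_cost 0) and resource-rational
# (max_cost 0.5) regimes. Shared fields apply to every condition.
n_steps: 150
n_iterations: 1000
n_individuals: 500
belief_sd: 0.1
proposal_sd: 0.05
prior: unimodal
seed: 1
conditions:
  - {c_prop: 0.55, max_cost: 0.0}
  - {c_prop: 0.55, max_cost: 0.5}
  - {c_prop: 0.65, max_cost: 0.0}
  - {c_prop: 0.65, max_cost: 0.5}
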