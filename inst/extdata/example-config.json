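{
  "topology": "smallworld",
  "n_nodes": 100,
  "k_nn": 4,
  "p_rew": 0.05,
  "scheme": "varied_position",
  "trials": 200,
  "rng_seed": 42,
  "fast": true
}
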