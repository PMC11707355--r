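{
  "seed": 42,
  "protocols": ["E_24", "T_12", "HF_8"],
  "quality": {"E_24": 0.9, "T_12": 0.7, "HF_8": 0.4},
  "grid_shape": [8, 8],
  "k": 2,
  "n_batches": 2,
  "n_observers": 2,
  "disagreement_sd": 0.1,
  "noise_sd": 2,
  "cosmic_ray_rate": 0.05,
  "snip_iterations": 400,
  "despike_z": 8
}
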