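{
  "size_class": "small",
  "extinction_level": "low",
  "modes": ["ETD", "CTD", "CR"],
  "n_replicates": 20,
  "sf_levels": [1, 0.6, 0.4],
  "regime": "random",
  "misspec": false,
  "seed": 1,
  "models_to_fit": ["CR", "CTD", "ETD"],
  "fit_control": {"maxit": 250},
  "ode_rel_tol": 1e-06,
  "ode_abs_tol": 1e-08
}
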