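{
  "_comment": "Full study-scale arm (cluster-scale compute: ~100 trees per generating mode, all SF levels, complete mis-specification grid). Run per size class / extinction level / regime.",
  "size_class": "medium",
  "extinction_level": "low",
  "modes": ["ETD", "CTD", "CR"],
  "n_replicates": 100,
  "sf_levels": [1, 0.8, 0.6, 0.4, 0.2],
  "regime": "random",
  "misspec": true,
  "seed": 1,
  "models_to_fit": ["CR", "CTD", "ETD"],
  "fit_control": {},
  "ode_rel_tol": 1e-08,
  "ode_abs_tol": 1e-10
}
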