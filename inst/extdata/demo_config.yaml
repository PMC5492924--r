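# Demonstration pipeline configuration: a small synthetic cohort with
# planted genus-environment preferences (odds multiplier 10) covering
# ubiquities 1..5, plus two preference-free genera.
alpha: 0.01
n_random_tables: 25
r2_threshold: 0.7
min_bins: 4
synthetic:
  n_genera: 12
  genomes_per_genus: [2, 4]
  n_environments: 5
  samples_per_environment: 40
  baseline_detection_prob: 0.03
  size_intercept: 3000000
  size_slope_per_env: 200000
  size_noise_sd: 400000
  n_cogs: 60
  n_adaptive_cogs: 6
  adaptive_presence_range: [0.1, 0.9]
  preference_map:
    genus: [g001, g002, g002, g003, g003, g003, g004, g004, g004, g004,
            g005, g005, g005, g005, g005, g006, g007, g007, g008, g008,
            g008, g009, g009, g009, g009, g010, g010, g010, g010, g010]
    environment: [env1, env1, env2, env1, env2, env3, env1, env2, env3,
                  env4, env1, env2, env3, env4, env5, env1, env1, env2,
                  env1, env2, env3, env1, env2, env3, env4, env1, env2,
                  env3, env4, env5]
    multiplier: [10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10,
                 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 10,
                 10, 10]
  rrna_regime_map:
    environment: [env1, env2, env3, env4, env5]
    mean_copies: [6, 5, 4, 3, 2]
    dispersion: [1.5, 1.5, 1.5, 1.5, 1.0]
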