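# Demonstration pipeline configuration: synthetic data at the study
# conditions, physiology fit, compartmentalized FBA, and a shortened
# isotopic PSO fit (increase iterations/swarm to 2000/50 for a full run).
seed: 1
stages: [synthetic, physiology, fba, isotopic]
design:
  t_start: 0
  t_end: 11
  n_points: 12
  n_replicates: 3
  noise_cv: 0.02
  noise_floor: 0.02
physiology:
  n_starts: 10
fba:
  objective: ATPM
isotopic:
  iterations: 300
  swarm: 40
  tracer_purity: 1.0
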