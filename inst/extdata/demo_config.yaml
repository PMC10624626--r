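# Demo run: tiny world, short horizon, few Monte Carlo draws.
# Finishes in well under a minute on one CPU.
seed: 7
out_dir: fishcast_demo_out
world:
  n_eez: 6
  grid_rows: 9
  grid_cols: 18
years:
  history: [1991, 2014]
  projection: [1991, 2050]
  reference: [1991, 2010]
species:
  n_species: 16
  warm_affiliated: true
nutrients:
  missingness: 0.2
monte_carlo:
  draws: 50
dbem:
  spinup_years: 40
trends:
  horizons: [2050]
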