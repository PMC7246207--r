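# Demo configuration for the pyronet pipeline (flat key = value, TOML dialect).
# A deliberately small landscape and community so the `all` subcommand runs in
# seconds; see ?sim_params for the meaning and defaults of each knob.

n_sites = 8
n_rounds_per_year = 4
severe_year = "2013"
extreme_year = "2014"
grid_size = 40
cell_size_m = 30
n_fires = 3
n_severity_classes = 4
n_plants = 14
n_pollinators = 18
richness_slope = 6
drought_bloom_factor = 0.5
beta_interaction = 1.5
noise_sd = 0.3
radius = 150
seed = 42
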