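# flimlag run configuration (all fields optional; defaults shown)
seed: 1
n_components: 2          # exponential components N
# tau_ranges:            # per-component lifetime ranges in ns (defaults: see ?sim_config)
#   - [0.05, 1.5]
#   - [1.0, 7.0]
# alpha_ranges:          # pre-rescale abundance ranges (default [0.05, 1] each)
nx: 128                  # simulated cube width
ny: 128                  # simulated cube height
m_train: 3000            # training traces
peak_scale: 150          # simulated peak photon counts
noise: true              # Poisson noise
trim: [40, 960]          # retained raw bins (1-based inclusive, for 1024-channel data)
mask_threshold: 9        # minimum per-pixel maximum count
orders: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15]
laguerre_alpha: 2
x_scale: 1               # Laguerre argument = x_scale * t(ns)
n_pca: 15
num_trees: 500
mtry: 12
sample_fraction: 0.632
irf:
  type: gaussian
  center: 0.5            # ns
  sigma: 0.05            # ns
  # file: irf.csv        # a measured IRF (two-column CSV) overrides the gaussian
# cube: cube.tiff        # for predict
# bundle: bundle.rds     # for predict
# truth: truth.csv       # for evaluate
# maps: maps.csv         # for evaluate
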