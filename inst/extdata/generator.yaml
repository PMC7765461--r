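# Example synthetic-canopy configuration: four sites with modest
# site effects, realistic noise, narrowband perturbations on.
n_samples: 500
biomass_range: [100, 4000]
noise_sd: 0.005
narrowband: true
seed: 1
locations:
  - {label: Elliot}
  - {label: Goutum, biomass_shift: 500, spectral_offset: 0.008}
  - {label: Vredepeel, biomass_shift: -500, spectral_offset: -0.008}
  - {label: Zegveld, biomass_shift: 250, spectral_offset: 0.004}
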