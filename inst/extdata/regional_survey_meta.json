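{
  "description": "Metadata of the published Central African plot network from which the packaged biomass-hyperdominance table was transcribed.",
  "n_recorded_species": 1194,
  "n_sites": 8,
  "n_plots": 175,
  "plot_area_ha": 1,
  "dbh_threshold_cm": 10
}
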