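# "Paper-like" simulation scenario: the default study conditions of the
# synthetic-data generator, written out in full so they can be edited.
seed: 1
forms: [white, pink]
phenology:
  n_plants: {white: 77, pink: 40}
  window:
    white: ["2016-07-24", "2016-08-31"]
    pink: ["2016-07-31", "2016-09-05"]
  flower_lifespan_mean: 10
  flower_lifespan_sd: 2
foraging:
  availability: {white: 20, pink: 20}
  species:
    - {species: apis_like, kappa: 0.95, n_foragers: 30, bout_mean: 10}
    - {species: bombus_like, kappa: 0.85, n_foragers: 26, bout_mean: 10}
crossing:
  n_per_cell: 30
  seeds_per_fruit: 300
  tube_dispersion: 1.5
  tube_mean:
    white: {self: 146.3, intraform: 118.93, interform: 125.62}
    pink: {self: 42.33, intraform: 83.95, interform: 69.75}
  fruit_p:
    white: {self: 0.8, intraform: 0.8, interform: 0.35, control: 0}
    pink: {self: 0.76, intraform: 0.76, interform: 0.67, control: 0}
  embryo_p:
    white:
      self: {large: 0.7194, small: 0.11, aborted: 0.09, empty: 0.0806}
      intraform: {large: 0.7242, small: 0.11, aborted: 0.09, empty: 0.0758}
      interform: {large: 0.4551, small: 0.22, aborted: 0.16, empty: 0.1649}
    pink:
      self: {large: 0.5085, small: 0.20, aborted: 0.15, empty: 0.1415}
      intraform: {large: 0.6548, small: 0.14, aborted: 0.10, empty: 0.1052}
      interform: {large: 0.6335, small: 0.15, aborted: 0.11, empty: 0.1065}
spectra:
  n: {white: 35, pink: 31, intermediate: 10}
  noise_sd: 0.005
  intermediate_weight: 0.75
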