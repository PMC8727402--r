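# Example scenario configuration: three synthetic sites, one cultivar,
# early/mid/late sowing windows. Weather entries take synthetic_spec()
# arguments; soil entries take soil_profile() arguments.
seed: 1
years: [1990, 2019]
sowing_windows:
  early: ["04-10", "04-30"]
  mid: ["05-01", "05-21"]
  late: ["05-22", "06-11"]
frost:
  loss_per_event: 0.05
  mode: multiplicative
grid:
  lo: 0.0
  hi: 19.0
  step: 0.1
cultivars:
  hattrick: hattrick
locations:
  - name: south_inland
    latitude: -35.0
    longitude: 147.0
    weather:
      temp_mean_annual: 16.0
      temp_seasonal_amplitude: 8.5
      diurnal_range_mean: 13.0
    soil:
      thickness: [150, 150, 300, 300]
      ll15: [20, 20, 45, 45]
      dul: [45, 45, 95, 95]
      sat: [55, 55, 115, 115]
  - name: mid_slopes
    latitude: -33.0
    longitude: 148.5
    weather:
      temp_mean_annual: 17.0
      temp_seasonal_amplitude: 8.0
      diurnal_range_mean: 13.0
    soil:
      thickness: [150, 150, 300, 300]
      ll15: [20, 20, 45, 45]
      dul: [45, 45, 95, 95]
      sat: [55, 55, 115, 115]
  - name: north_plains
    latitude: -30.0
    longitude: 150.0
    weather:
      temp_mean_annual: 18.5
      temp_seasonal_amplitude: 7.5
      diurnal_range_mean: 13.5
    soil:
      thickness: [150, 150, 300, 300]
      ll15: [22, 22, 48, 48]
      dul: [46, 46, 96, 96]
      sat: [56, 56, 116, 116]
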