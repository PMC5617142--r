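# Example pipeline configuration: a small synthetic network.
seed: 1
threshold_percent: 30
linkage: complete
eeq_flag_levels: [1, 10]
generator:
  n_rivers: 6
  sites_per_river: 4
  visits_per_site: 2
  sediment_visits: 1
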