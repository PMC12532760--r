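# Example synthetic land-cover scenario: a 100x100-cell world (1 km cells)
# in which forest retreats along its boundaries and unmanaged
# grass/shrubland expands, 1992-2020.
grid_rows: 100
grid_cols: 100
cell_size_km: 1
ocean_fraction: 0.1
cluster_density: 0.35
seed: 1
years: [1992, 2020]
classes:
  - {code: 11, name: urban, proportion: 0.02}
  - {code: 22, name: cropland, proportion: 0.13}
  - {code: 33, name: pasture_rangeland, proportion: 0.20}
  - {code: 44, name: forest, proportion: 0.30}
  - {code: 55, name: grass_shrubland, proportion: 0.20}
  - {code: 66, name: sparse_vegetation, proportion: 0.15}
operators:
  - {kind: contract, source: 44, target: 33, rate: 25}
  - {kind: expand, source: 55, rate: 20}
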