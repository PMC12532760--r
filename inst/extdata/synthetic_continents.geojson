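{
  "type": "FeatureCollection",
  "note": "Synthetic quadrant 'continents' for the 100x100 km example world; coordinates are projected km, not real geography.",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "Northwest"},
      "geometry": {"type": "Polygon", "coordinates": [[[0, 50], [50, 50], [50, 100], [0, 100], [0, 50]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Northeast"},
      "geometry": {"type": "Polygon", "coordinates": [[[50, 50], [100, 50], [100, 100], [50, 100], [50, 50]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Southwest"},
      "geometry": {"type": "Polygon", "coordinates": [[[0, 0], [50, 0], [50, 50], [0, 50], [0, 0]]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Southeast"},
      "geometry": {"type": "Polygon", "coordinates": [[[50, 0], [100, 0], [100, 50], [50, 50], [50, 0]]]}
    }
  ]
}
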