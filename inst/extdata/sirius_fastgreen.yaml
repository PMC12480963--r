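# Default Sirius Red / Fast Green stain model: unit optical-density vectors
# (R, G, B) per stain, background white point, OD intensity floor.
stain_names: [sirius_red, fast_green]
stain_od_vectors:
  - [0.10, 0.72, 0.69]
  - [0.70, 0.12, 0.70]
background_intensity: [255, 255, 255]
od_floor: 0.5
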