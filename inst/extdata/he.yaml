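# Classical Ruifrok-Johnston haematoxylin / eosin absorption vectors.
stain_names: [haematoxylin, eosin]
stain_od_vectors:
  - [0.650, 0.704, 0.286]
  - [0.072, 0.990, 0.105]
background_intensity: [255, 255, 255]
od_floor: 0.5
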