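water_to_tissue: 0.992
plastic_water:
  Dmm:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
  Dww:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
cortical_bone:
  Dmm:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
  Dww:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
trabecular_bone:
  Dmm:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
  Dww:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
inhale_lung:
  Dmm:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
  Dww:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
lung_target:
  Dmm:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
  Dww:
    factor: 1.0
    provenance: placeholder unity factor; supply measured values
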