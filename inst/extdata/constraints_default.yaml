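version: '1.0'
theory: QF_LRA
rules:
- id: C1
  antecedent_class: glioma
  feature: enhancement_variance
  comparator: '>'
  threshold: 0.1
  description: glioma implies heterogeneous enhancement (in-mask intensity variance)
- id: C2
  antecedent_class: pituitary
  feature: sellar_band_overlap
  comparator: '>'
  threshold: 0.5
  description: pituitary implies proximity to the sella turcica (central y-band overlap)
- id: C3
  antecedent_class: meningioma
  feature: border_edge_density
  comparator: '>'
  threshold: 0.05
  description: meningioma implies dural contact proxy (border-band edge density)
- id: C4
  antecedent_class: glioma
  feature: enhancement_variance
  comparator: '>'
  threshold: 0.1
  description: 'consistency invariant: no glioma prediction in the absence of heterogeneous
    enhancement'
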