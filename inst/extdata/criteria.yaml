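criteria:
  - name: biomass
    direction: 1
    rank: 1
  - name: protein
    direction: 1
    rank: 2
  - name: surface_tension
    direction: -1
    rank: 3
  - name: clear_zone
    direction: 1
    rank: 4
quantizer: log
lambda_method: row_ratio
cr_threshold: 0.1
normalization: colsum
factors:
  - name: lactose
    center: 5
    step: 2
  - name: yeast_extract
    center: 6
    step: 3
  - name: NaCl
    center: 20
    step: 5
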