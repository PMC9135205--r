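genes:
- name: geneX
  length: 150
- name: geneY
  length: 150
- name: geneZ
  length: 150
elements:
- kind: promoter
  region: 0
  strength: 1000000.0
- kind: promoter
  region: 1
  strength: 1000000.0
- kind: rnase_site
  region: 1
  strength: 0.005
- kind: terminator
  region: 2
  strength: 0.2
- kind: terminator
  region: 3
  strength: 0.2
spacer_length: 50
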