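# Default sex vocabulary (4 types).
axis: sex
unknown_label: uncharacterized
terms:
  - term: female
    synonyms: [f]
  - term: male
    synonyms: [m]
  - term: mixed
    synonyms: [mixed sex, pooled, both]
  - term: undetermined
    synonyms: [not determined, nd]
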