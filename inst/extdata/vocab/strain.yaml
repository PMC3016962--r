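# Default Bombyx mori strain vocabulary (10 strains).
axis: strain
unknown_label: uncharacterized
terms:
  - term: Dazao
    synonyms: [p50, dazao (p50)]
  - term: C108
  - term: Nistari
  - term: "306"
  - term: Qiufeng
  - term: Baiyu
  - term: "871"
  - term: "872"
  - term: Haoyue
  - term: N4
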