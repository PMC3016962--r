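# Default Bombyx mori tissue vocabulary (28 canonical tissue/organ types).
# Editable data: replace or extend for other species.
axis: tissue
unknown_label: uncharacterized
terms:
  - term: ovary
    synonyms: [ovaries, ovarian tissue]
  - term: silk gland
    synonyms: [silkgland, sg, whole silk gland]
  - term: middle silk gland
    synonyms: [msg, mid silk gland, middle silkgland]
  - term: posterior silk gland
    synonyms: [psg, posterior silkgland]
  - term: anterior silk gland
    synonyms: [asg]
  - term: wing disk
    synonyms: [wing disc, wing imaginal disc, wing imaginal disk]
  - term: fat body
    synonyms: [fatbody]
  - term: microbe-infected fat body
    synonyms: [infected fat body, immunized fat body]
  - term: pheromone gland
    synonyms: [phg]
  - term: prothoracic gland
    synonyms: [ptg]
  - term: midgut
    synonyms: [mid gut, mesenteron]
  - term: head
    synonyms: [heads]
  - term: malpighian tubule
    synonyms: [malpighian tubules, mt]
  - term: testis
    synonyms: [testes]
  - term: brain
  - term: epidermis
  - term: hemocyte
    synonyms: [hemocytes, haemocyte]
  - term: integument
  - term: muscle
  - term: trachea
  - term: compound eye
    synonyms: [eye]
  - term: antenna
    synonyms: [antennae]
  - term: egg
    synonyms: [eggs]
  - term: ovary-derived cell line
    synonyms: [bmn cell, ovary cell line]
  - term: bmnpv-infected ovary cell
    synonyms: [npv-infected ovary cell]
  - term: embryo
    synonyms: [embryos]
  - term: maxillary gland
  - term: whole body
    synonyms: [whole larva, whole insect, whole-body]
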