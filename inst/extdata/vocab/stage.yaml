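# Default Bombyx mori developmental-stage vocabulary (31 canonical stages,
# listed in temporal order; figures and tables keep this order).
axis: stage
unknown_label: uncharacterized
terms:
  - term: egg day 1
  - term: egg day 5
  - term: embryo
    synonyms: [embryonic stage]
  - term: 1st instar
    synonyms: [first instar, instar 1]
  - term: 2nd instar
    synonyms: [second instar, instar 2]
  - term: 3rd instar
    synonyms: [third instar, instar 3]
  - term: 4th instar day 1
  - term: 4th instar day 2
    synonyms: [4th-instar day 2, day 2 of 4th instar]
  - term: 4th instar day 3
  - term: 4th instar molting
    synonyms: [4th molting]
  - term: 5th instar day 1
  - term: 5th instar day 2
  - term: 5th instar day 3
    synonyms: [5th-instar day 3, day 3 of 5th instar, 5th instar d3]
  - term: 5th instar day 4
  - term: 5th instar day 5
  - term: 5th instar day 6
  - term: 5th instar day 7
  - term: 5th instar
    synonyms: [fifth instar]
  - term: 5th instar to spinning
    synonyms: [5th instar-spinning, 5th instar to spinning mixture]
  - term: spinning
    synonyms: [spinning stage, spinning larva]
  - term: wandering
    synonyms: [wandering stage]
  - term: prepupa
    synonyms: [pre-pupa]
  - term: pupa day 1
  - term: pupa day 3
  - term: pupa day 5
    synonyms: [day 5 pupa]
  - term: pupa day 7
  - term: pupa
    synonyms: [pupal stage, pupae]
  - term: adult day 1
  - term: adult
    synonyms: [moth, imago]
  - term: mixed stages
    synonyms: [mixed stage, multiple stages]
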