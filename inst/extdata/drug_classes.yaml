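# Antiplatelet / anticoagulant class map. Drug names are matched after
# case-folding and whitespace collapsing; salt suffixes are part of the name.
alteplase:
  - alteplase
aspirin:
  - aspirin
P2Y12:
  - clopidogrel sulfate
  - ticagrelor
  - ticlopidine hydrochloride
  - prasugrel hydrochloride
cilostazol:
  - cilostazol
ozagrel:
  - ozagrel sodium
other_antiplatelet:
  - dipyridamole
  - limaprost alfadex
  - beraprost sodium
  - ethyl icosapentate
  - omega-3 fatty acid ethyl
  - sarpogrelate hydrochloride
  - dilazep hydrochloride hydrate
  - trapidil
DOAC:
  - apixaban
  - dabigatran etexilate methanesulfonate
  - edoxaban tosilate hydrate
  - rivaroxaban
warfarin:
  - warfarin potassium
heparin:
  - heparin sodium
  - heparin calcium
argatroban:
  - argatroban
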