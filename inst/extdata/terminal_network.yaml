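name: terminal
rules: terminal
factors:
- factor: Tll
  max_level: 2
  role: input
- factor: Hkb
  max_level: 2
  role: input
- factor: Cad
  max_level: 1
  role: output
- factor: D
  max_level: 2
  role: output
- factor: Opa
  max_level: 2
  role: output
- factor: Fkh
  max_level: 1
  role: output
- factor: Wg
  max_level: 1
  role: output
schedule:
  Hkb:
  - - 0
    - 0
    - 0
    - 0
  - - 0
    - 0
    - 0
    - 0
  - - 1
    - 1
    - 0
    - 0
  - - 2
    - 2
    - 2
    - 1
  Tll:
  - - 0
    - 0
    - 0
    - 0
  - - 1
    - 1
    - 0
    - 0
  - - 2
    - 2
    - 2
    - 0
  - - 2
    - 2
    - 2
    - 0
initial:
  Cad: 1
  D: 0
  Opa: 0
  Fkh: 0
  Wg: 0
genotypes:
  wt: []
  fkh-:
  - Fkh
  cad-:
  - Cad
  D-:
  - D
  opa-:
  - Opa
  tor-:
  - Tll
  - Hkb
  hkb-:
  - Hkb
  tll-:
  - Tll
  tll-opa-:
  - Tll
  - Opa
interactions:
- edge: Cad->D
  source: Cad
  target: D
  sign: activation
  directness: direct
  provenance: this_study
  threshold: 1
  functional: yes
- edge: D->Cad
  source: D
  target: Cad
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 1
  functional: yes
- edge: Opa->Cad
  source: Opa
  target: Cad
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 2
  functional: yes
- edge: Opa->D
  source: Opa
  target: D
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 2
  functional: yes
- edge: Tll->Cad
  source: Tll
  target: Cad
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 2
  functional: yes
- edge: Tll->D
  source: Tll
  target: D
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 1
  functional: yes
- edge: Tll->Opa
  source: Tll
  target: Opa
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 1
  functional: yes
- edge: Hkb->Cad
  source: Hkb
  target: Cad
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 2
  functional: yes
- edge: Hkb->D
  source: Hkb
  target: D
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 1
  functional: yes
- edge: Hkb->Opa
  source: Hkb
  target: Opa
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 2
  functional: yes
- edge: Hkb->Wg
  source: Hkb
  target: Wg
  sign: repression
  directness: direct
  provenance: this_study
  threshold: 2
  functional: yes
- edge: Fkh->Wg
  source: Fkh
  target: Wg
  sign: activation
  directness: direct
  provenance: literature
  threshold: 1
  functional: yes
- edge: Cad->Fkh
  source: Cad
  target: Fkh
  sign: activation
  directness: direct
  provenance: literature
  threshold: 1
  functional: yes
- edge: Tll->Fkh
  source: Tll
  target: Fkh
  sign: activation
  directness: indirect
  provenance: literature
  threshold: 2
  functional: yes
- edge: Hkb->Fkh
  source: Hkb
  target: Fkh
  sign: activation
  directness: indirect
  provenance: literature
  threshold: 2
  functional: yes
- edge: Fkh->Fkh
  source: Fkh
  target: Fkh
  sign: activation
  directness: direct
  provenance: literature
  threshold: 1
  functional: yes
- edge: Cad->Wg
  source: Cad
  target: Wg
  sign: activation
  directness: indirect
  provenance: literature
  threshold: 1
  functional: no
- edge: Tll->Wg
  source: Tll
  target: Wg
  sign: activation
  directness: indirect
  provenance: literature
  threshold: 2
  functional: no
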