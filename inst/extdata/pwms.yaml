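- name: TATA
  consensus: TATAWAAR
  frequencies:
  - - 0.05
    - 0.85
    - 0.05
    - 0.85
    - 0.425
    - 0.85
    - 0.85
    - 0.425
  - - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.075
    - 0.05
    - 0.05
    - 0.075
  - - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.075
    - 0.05
    - 0.05
    - 0.425
  - - 0.85
    - 0.05
    - 0.85
    - 0.05
    - 0.425
    - 0.05
    - 0.05
    - 0.075
  cutoff_fraction: 0.8
  expected_position: -31.0
  functional_halfwidth: 2
- name: BREu
  consensus: SSRCGCC
  frequencies:
  - - 0.075
    - 0.075
    - 0.425
    - 0.05
    - 0.05
    - 0.05
    - 0.05
  - - 0.425
    - 0.425
    - 0.075
    - 0.85
    - 0.05
    - 0.85
    - 0.85
  - - 0.425
    - 0.425
    - 0.425
    - 0.05
    - 0.85
    - 0.05
    - 0.05
  - - 0.075
    - 0.075
    - 0.075
    - 0.05
    - 0.05
    - 0.05
    - 0.05
  cutoff_fraction: 0.85
  expected_position: -38.0
  functional_halfwidth: 2
- name: BREd
  consensus: RTDKKKK
  frequencies:
  - - 0.425
    - 0.05
    - 0.283333
    - 0.075
    - 0.075
    - 0.075
    - 0.075
  - - 0.075
    - 0.05
    - 0.15
    - 0.075
    - 0.075
    - 0.075
    - 0.075
  - - 0.425
    - 0.05
    - 0.283333
    - 0.425
    - 0.425
    - 0.425
    - 0.425
  - - 0.075
    - 0.85
    - 0.283333
    - 0.425
    - 0.425
    - 0.425
    - 0.425
  cutoff_fraction: 0.85
  expected_position: -23.0
  functional_halfwidth: 2
- name: Inr
  consensus: YYANWYY
  frequencies:
  - - 0.075
    - 0.075
    - 0.85
    - 0.25
    - 0.425
    - 0.075
    - 0.075
  - - 0.425
    - 0.425
    - 0.05
    - 0.25
    - 0.075
    - 0.425
    - 0.425
  - - 0.075
    - 0.075
    - 0.05
    - 0.25
    - 0.075
    - 0.075
    - 0.075
  - - 0.425
    - 0.425
    - 0.05
    - 0.25
    - 0.425
    - 0.425
    - 0.425
  cutoff_fraction: 0.85
  expected_position: -2.0
  functional_halfwidth: 2
- name: DPE
  consensus: RGWYV
  frequencies:
  - - 0.425
    - 0.05
    - 0.425
    - 0.075
    - 0.283333
  - - 0.075
    - 0.05
    - 0.075
    - 0.425
    - 0.283333
  - - 0.425
    - 0.85
    - 0.075
    - 0.075
    - 0.283333
  - - 0.075
    - 0.05
    - 0.425
    - 0.425
    - 0.15
  cutoff_fraction: 0.9
  expected_position: 28.0
  functional_halfwidth: 2
  requires: Inr
- name: MTE
  consensus: CSARCSSAAC
  frequencies:
  - - 0.05
    - 0.075
    - 0.85
    - 0.425
    - 0.05
    - 0.075
    - 0.075
    - 0.85
    - 0.85
    - 0.05
  - - 0.85
    - 0.425
    - 0.05
    - 0.075
    - 0.85
    - 0.425
    - 0.425
    - 0.05
    - 0.05
    - 0.85
  - - 0.05
    - 0.425
    - 0.05
    - 0.425
    - 0.05
    - 0.425
    - 0.425
    - 0.05
    - 0.05
    - 0.05
  - - 0.05
    - 0.075
    - 0.05
    - 0.075
    - 0.05
    - 0.075
    - 0.075
    - 0.05
    - 0.05
    - 0.05
  cutoff_fraction: 0.8
  expected_position: 18.0
  functional_halfwidth: 2
- name: DCE_I
  consensus: CTTC
  frequencies:
  - - 0.05
    - 0.05
    - 0.05
    - 0.05
  - - 0.85
    - 0.05
    - 0.05
    - 0.85
  - - 0.05
    - 0.05
    - 0.05
    - 0.05
  - - 0.05
    - 0.85
    - 0.85
    - 0.05
  cutoff_fraction: 0.95
  expected_position: 6.0
  functional_halfwidth: 2
- name: DCE_II
  consensus: CTGT
  frequencies:
  - - 0.05
    - 0.05
    - 0.05
    - 0.05
  - - 0.85
    - 0.05
    - 0.05
    - 0.05
  - - 0.05
    - 0.05
    - 0.85
    - 0.05
  - - 0.05
    - 0.85
    - 0.05
    - 0.85
  cutoff_fraction: 0.95
  expected_position: 16.0
  functional_halfwidth: 2
- name: DCE_III
  consensus: AGC
  frequencies:
  - - 0.85
    - 0.05
    - 0.05
  - - 0.05
    - 0.05
    - 0.85
  - - 0.05
    - 0.85
    - 0.05
  - - 0.05
    - 0.05
    - 0.05
  cutoff_fraction: 0.95
  expected_position: 30.0
  functional_halfwidth: 2
- name: XCPE1
  consensus: DSGYGGRASM
  frequencies:
  - - 0.283333
    - 0.075
    - 0.05
    - 0.075
    - 0.05
    - 0.05
    - 0.425
    - 0.85
    - 0.075
    - 0.425
  - - 0.15
    - 0.425
    - 0.05
    - 0.425
    - 0.05
    - 0.05
    - 0.075
    - 0.05
    - 0.425
    - 0.425
  - - 0.283333
    - 0.425
    - 0.85
    - 0.075
    - 0.85
    - 0.85
    - 0.425
    - 0.05
    - 0.425
    - 0.075
  - - 0.283333
    - 0.075
    - 0.05
    - 0.425
    - 0.05
    - 0.05
    - 0.075
    - 0.05
    - 0.075
    - 0.075
  cutoff_fraction: 0.8
  expected_position: -8.0
  functional_halfwidth: 2
- name: TCT
  consensus: YYCTTTYY
  frequencies:
  - - 0.075
    - 0.075
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.075
    - 0.075
  - - 0.425
    - 0.425
    - 0.85
    - 0.05
    - 0.05
    - 0.05
    - 0.425
    - 0.425
  - - 0.075
    - 0.075
    - 0.05
    - 0.05
    - 0.05
    - 0.05
    - 0.075
    - 0.075
  - - 0.425
    - 0.425
    - 0.05
    - 0.85
    - 0.85
    - 0.85
    - 0.425
    - 0.425
  cutoff_fraction: 0.85
  expected_position: -2.0
  functional_halfwidth: 2
- name: PauseButton
  consensus: KCGRWCG
  frequencies:
  - - 0.075
    - 0.05
    - 0.05
    - 0.425
    - 0.425
    - 0.05
    - 0.05
  - - 0.075
    - 0.85
    - 0.05
    - 0.075
    - 0.075
    - 0.85
    - 0.05
  - - 0.425
    - 0.05
    - 0.85
    - 0.425
    - 0.075
    - 0.05
    - 0.85
  - - 0.425
    - 0.05
    - 0.05
    - 0.075
    - 0.425
    - 0.05
    - 0.05
  cutoff_fraction: 0.85
  expected_position: 25.0
  functional_halfwidth: 2
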