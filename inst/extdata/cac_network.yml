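nodes:
- name: P53
  g: 1.0
  k: 1.0
  is_input: no
- name: MDM2
  g: 0.6
  k: 1.0
  is_input: no
- name: miR34
  g: 1.0
  k: 1.0
  is_input: no
- name: miR145
  g: 1.0
  k: 1.0
  is_input: no
- name: miR200
  g: 1.0
  k: 1.0
  is_input: no
- name: SNAIL1
  g: 1.0
  k: 1.0
  is_input: no
- name: ZEB1
  g: 0.45
  k: 1.0
  is_input: no
- name: LIN28
  g: 0.8
  k: 1.0
  is_input: no
- name: LET7
  g: 1.0
  k: 1.0
  is_input: no
- name: BACH1
  g: 0.8
  k: 1.0
  is_input: no
- name: RKIP
  g: 1.0
  k: 1.0
  is_input: no
- name: MEK
  g: 1.5
  k: 1.0
  is_input: no
- name: ERK
  g: 0.5
  k: 1.0
  is_input: no
- name: PPARG
  g: 0.5
  k: 1.0
  is_input: no
- name: CEBPA
  g: 0.3
  k: 1.0
  is_input: no
- name: TGFB
  g: 0.0
  k: 1.0
  is_input: yes
- name: MEKI
  g: 0.0
  k: 1.0
  is_input: yes
- name: ROSI
  g: 0.0
  k: 1.0
  is_input: yes
edges:
- source: TGFB
  target: SNAIL1
  lambda: 3.5
  S: 4.0
  'n': 2.0
  side: G
- source: TGFB
  target: ZEB1
  lambda: 1.8
  S: 4.5
  'n': 3.0
  side: G
- source: SNAIL1
  target: ZEB1
  lambda: 2.56
  S: 1.5
  'n': 2.0
  side: G
- source: ZEB1
  target: ZEB1
  lambda: 2.8
  S: 2.0
  'n': 4.0
  side: G
- source: miR200
  target: ZEB1
  lambda: 0.08
  S: 0.6
  'n': 4.0
  side: G
- source: miR145
  target: ZEB1
  lambda: 0.15
  S: 0.9
  'n': 4.0
  side: G
- source: ZEB1
  target: miR200
  lambda: 0.1
  S: 0.45
  'n': 4.0
  side: G
- source: SNAIL1
  target: miR200
  lambda: 0.5
  S: 1.256
  'n': 2.0
  side: G
- source: ZEB1
  target: miR145
  lambda: 0.2
  S: 1.8
  'n': 4.0
  side: G
- source: SNAIL1
  target: miR145
  lambda: 0.5
  S: 1.256
  'n': 2.0
  side: G
- source: miR34
  target: SNAIL1
  lambda: 0.4
  S: 0.8
  'n': 2.0
  side: G
- source: SNAIL1
  target: miR34
  lambda: 0.4
  S: 1.2
  'n': 2.0
  side: G
- source: ZEB1
  target: miR34
  lambda: 0.6
  S: 1.5
  'n': 2.0
  side: G
- source: miR200
  target: SNAIL1
  lambda: 0.7
  S: 0.8
  'n': 2.0
  side: G
- source: P53
  target: miR145
  lambda: 2.0
  S: 0.8
  'n': 2.0
  side: G
- source: P53
  target: miR200
  lambda: 2.0
  S: 0.8
  'n': 2.0
  side: G
- source: P53
  target: miR34
  lambda: 2.0
  S: 0.8
  'n': 2.0
  side: G
- source: P53
  target: MDM2
  lambda: 2.0
  S: 0.8
  'n': 2.0
  side: G
- source: MDM2
  target: P53
  lambda: 2.5
  S: 0.6
  'n': 2.0
  side: K
- source: SNAIL1
  target: P53
  lambda: 0.45
  S: 1.2
  'n': 2.0
  side: G
- source: miR34
  target: P53
  lambda: 1.5
  S: 0.5
  'n': 2.0
  side: G
- source: miR145
  target: MDM2
  lambda: 0.5
  S: 0.5
  'n': 2.0
  side: G
- source: LIN28
  target: LET7
  lambda: 0.3
  S: 0.6
  'n': 2.0
  side: G
- source: LET7
  target: LIN28
  lambda: 0.3
  S: 0.6
  'n': 2.0
  side: G
- source: LET7
  target: BACH1
  lambda: 0.4
  S: 0.7
  'n': 2.0
  side: G
- source: BACH1
  target: RKIP
  lambda: 0.4
  S: 0.7
  'n': 2.0
  side: G
- source: SNAIL1
  target: RKIP
  lambda: 0.3
  S: 1.2
  'n': 2.0
  side: G
- source: LET7
  target: SNAIL1
  lambda: 0.7
  S: 0.8
  'n': 2.0
  side: G
- source: ZEB1
  target: LIN28
  lambda: 1.6
  S: 1.5
  'n': 2.0
  side: G
- source: miR200
  target: CEBPA
  lambda: 0.25
  S: 0.7
  'n': 4.0
  side: G
- source: P53
  target: LET7
  lambda: 1.6
  S: 0.8
  'n': 2.0
  side: G
- source: BACH1
  target: LET7
  lambda: 0.5
  S: 0.7
  'n': 2.0
  side: G
- source: RKIP
  target: MEK
  lambda: 0.5
  S: 0.8
  'n': 2.0
  side: G
- source: MEKI
  target: MEK
  lambda: 0.1
  S: 0.01
  'n': 2.0
  side: G
- source: ERK
  target: MEK
  lambda: 0.7
  S: 2.0
  'n': 2.0
  side: G
- source: MEK
  target: ERK
  lambda: 4.0
  S: 1.5
  'n': 2.0
  side: G
- source: ERK
  target: ERK
  lambda: 1.5
  S: 1.2
  'n': 4.0
  side: G
- source: ERK
  target: ERK
  lambda: 0.6
  S: 3.0
  'n': 4.0
  side: G
- source: TGFB
  target: MEK
  lambda: 1.5
  S: 4.0
  'n': 2.0
  side: G
- source: BACH1
  target: MEK
  lambda: 1.3
  S: 0.8
  'n': 2.0
  side: G
- source: ERK
  target: SNAIL1
  lambda: 1.4
  S: 1.5
  'n': 2.0
  side: G
- source: ERK
  target: ZEB1
  lambda: 1.8
  S: 1.5
  'n': 2.0
  side: G
- source: SNAIL1
  target: CEBPA
  lambda: 0.25
  S: 1.8
  'n': 4.0
  side: G
- source: PPARG
  target: CEBPA
  lambda: 4.0
  S: 1.8
  'n': 6.0
  side: G
- source: CEBPA
  target: PPARG
  lambda: 4.5
  S: 1.1
  'n': 4.0
  side: G
- source: ROSI
  target: PPARG
  lambda: 3.5
  S: 0.5
  'n': 2.0
  side: G
- source: ERK
  target: PPARG
  lambda: 0.1
  S: 0.8
  'n': 2.0
  side: G
- source: SNAIL1
  target: PPARG
  lambda: 0.15
  S: 1.7
  'n': 6.0
  side: G
- source: ZEB1
  target: CEBPA
  lambda: 3.5
  S: 0.75
  'n': 2.0
  side: G
- source: PPARG
  target: PPARG
  lambda: 1.5
  S: 1.5
  'n': 4.0
  side: G
- source: PPARG
  target: SNAIL1
  lambda: 0.98
  S: 4.0
  'n': 4.0
  side: G
- source: PPARG
  target: ZEB1
  lambda: 0.98
  S: 4.0
  'n': 4.0
  side: G
inputs:
  TGFB: 1.0
  MEKI: 0.001
  ROSI: 0.1
phenotype_rules:
  ppar_on: 1.7
  ppar_high: 2.5
  zeb_mid: 0.35
  zeb_high: 2.5
  p53_high: 0.55
meta:
  description: 'Cancer-adipose conversion (CAC) regulatory network: synthetic reconstruction
    of the published circuit wiring with kinetic parameters calibrated against the
    reported attractor structure under the printed drug conditions.'
  calibration: Monostable E without drugs; E/M bistability at moderate TGFB; E/M/P1
    with MEKi; five states (E,M,P1,P2,A) with TGFB=4.3, MEKi=0.02, Rosi=1.5; monostable
    M at TGFB=8; TGFB fold cascade 1-2-3-4-5-4-3-2-1 with E-only ending near 3.2 and
    M-only starting near 7.5; ZEB1-activation+Rosi 500x gives monostable A, SNAIL1-activation+Rosi
    500x monostable M.

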