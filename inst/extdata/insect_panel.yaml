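classes:
- cricket
- buffalo_worm
- mealworm
n_per_class:
  cricket: 24
  buffalo_worm: 24
  mealworm: 28
within_class_cv: 0.1
elements:
- element: 10B
  lod: 5.0
  loq: 17.0
  means:
    cricket: 2.5
    buffalo_worm: 2.5
    mealworm: 2.5
  censor:
    cricket: below_lod
    buffalo_worm: below_lod
    mealworm: below_lod
- element: 23Na
  lod: 3.0
  loq: 9.0
  means:
    cricket: 2900.0
    buffalo_worm: 1760.0
    mealworm: 560.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 24Mg
  lod: 4.5
  loq: 15.0
  means:
    cricket: 464.0
    buffalo_worm: 550.0
    mealworm: 1160.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 27Al
  lod: 0.8
  loq: 3.0
  means:
    cricket: 260.0
    buffalo_worm: 220.0
    mealworm: 80.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 31P
  lod: 0.2
  loq: 0.7
  means:
    cricket: 8400.0
    buffalo_worm: 7200.0
    mealworm: 6800.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 39K
  lod: 23.0
  loq: 73.0
  means:
    cricket: 10000.0
    buffalo_worm: 11400.0
    mealworm: 9800.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 44Ca
  lod: 120.0
  loq: 393.0
  means:
    cricket: 1220.0
    buffalo_worm: 680.0
    mealworm: 380.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 52Cr
  lod: 0.02
  loq: 0.07
  means:
    cricket: 0.2
    buffalo_worm: 0.4
    mealworm: 0.045
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: below_loq
- element: 55Mn
  lod: 0.3
  loq: 1.0
  means:
    cricket: 46.6
    buffalo_worm: 6.6
    mealworm: 13.4
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 56Fe
  lod: 0.0002
  loq: 0.0007
  means:
    cricket: 60.0
    buffalo_worm: 52.0
    mealworm: 56.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 57Fe
  lod: 0.004
  loq: 0.013
  means:
    cricket: 80.0
    buffalo_worm: 68.0
    mealworm: 78.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 59Co
  lod: 0.004
  loq: 0.013
  means:
    cricket: 0.04
    buffalo_worm: 0.06
    mealworm: 0.06
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 60Ni
  lod: 0.15
  loq: 0.5
  means:
    cricket: 0.6
    buffalo_worm: 0.6
    mealworm: 0.6
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 64Zn
  lod: 3.0
  loq: 9.0
  means:
    cricket: 320.0
    buffalo_worm: 130.0
    mealworm: 140.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 65Cu
  lod: 0.07
  loq: 0.2
  means:
    cricket: 38.0
    buffalo_worm: 38.0
    mealworm: 22.0
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 80Se
  lod: 0.07
  loq: 0.25
  means:
    cricket: 0.54
    buffalo_worm: 0.16
    mealworm: 0.28
  censor:
    cricket: observed
    buffalo_worm: below_loq
    mealworm: observed
- element: 88Sr
  lod: 0.5
  loq: 2.0
  means:
    cricket: 4.2
    buffalo_worm: 1.25
    mealworm: 3.24
  censor:
    cricket: observed
    buffalo_worm: below_loq
    mealworm: observed
- element: 98Mo
  lod: 0.04
  loq: 0.13
  means:
    cricket: 0.8
    buffalo_worm: 0.78
    mealworm: 1.42
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 111Cd
  lod: 0.01
  loq: 0.03
  means:
    cricket: 0.032
    buffalo_worm: 0.032
    mealworm: 0.048
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
- element: 138Ba
  lod: 0.04
  loq: 0.12
  means:
    cricket: 2.88
    buffalo_worm: 0.52
    mealworm: 3.3
  censor:
    cricket: observed
    buffalo_worm: observed
    mealworm: observed
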