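format: pd2loop backbone_ff v1
bonds:
  N-CA:
  - 1.458
  - 600.0
  CA-C:
  - 1.525
  - 600.0
  C-O:
  - 1.231
  - 1100.0
  C-N:
  - 1.329
  - 900.0
angles:
  N-CA-C:
  - 110.1
  - 120.0
  CA-C-O:
  - 120.4
  - 160.0
  CA-C-N:
  - 116.6
  - 140.0
  O-C-N:
  - 122.9
  - 160.0
  C-N-CA:
  - 121.9
  - 100.0
torsions:
  phi:
  - 3.0
  - 0.0
  - 0.3
  psi:
  - 1.0
  - 180.0
  - 0.4
  omega:
  - 1.0
  - 0.0
  - 80.0
impropers:
  C-planar:
  - 180.0
  - 40.0
lj:
  'N':
  - 3.25
  - 0.17
  CA:
  - 3.8
  - 0.08
  C:
  - 3.75
  - 0.105
  O:
  - 2.96
  - 0.21
steric:
  r_rep: 2.8
  k_rep: 25.0
hbond:
  r_edges:
  - 1.4
  - 1.5
  - 1.6
  - 1.7
  - 1.8
  - 1.9
  - 2.0
  - 2.1
  - 2.2
  - 2.3
  - 2.4
  - 2.5
  - 2.6
  - 2.7
  - 2.8
  - 2.9
  - 3.0
  a_edges:
  - 90.0
  - 100.0
  - 110.0
  - 120.0
  - 130.0
  - 140.0
  - 150.0
  - 160.0
  - 170.0
  - 180.0
  values:
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.867648862553
    - 0.658358382012
    - 0.0
    - 0.0
    - 0.0
  - - 1.343743167087
    - 0.0
    - 0.0
    - 0.0
    - 1.000982137297
    - 0.0
    - 0.48626976567
    - -0.004070401446
    - 0.0
  - - 0.0
    - 1.437887453054
    - 0.0
    - 1.273070119055
    - 0.0
    - 0.0
    - 0.100444099479
    - 0.120929556129
    - 0.0
  - - 1.586390152158
    - 0.0
    - 1.491826402807
    - 0.0
    - 0.0
    - 0.0
    - 0.72891675074
    - -1.060706400505
    - -2.316192970352
  - - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.0
    - 0.298151869012
    - -1.005798852185
    - -2.312900155828
    - -2.684654963041
  - - 0.0
    - 1.771908708056
    - 1.197375006547
    - 0.0
    - 0.949177726108
    - -0.358725043102
    - -1.847917031196
    - -2.815884752668
    - -3.0
  - - 1.902764365767
    - 0.0
    - 0.0
    - 0.859793499773
    - 1.049177712211
    - -1.106022917386
    - -1.966970611156
    - -3.0
    - -3.0
  - - 0.0
    - 1.967146778509
    - 1.392613077
    - 0.0
    - -0.290668728729
    - -1.262099261317
    - -1.567521152403
    - -2.541658270896
    - -2.836138876397
  - - 0.0
    - 2.05805586079
    - 0.895735494379
    - 0.283800614357
    - 0.279813433814
    - -0.409050126989
    - -1.037245410338
    - -0.558185020265
    - -1.813671590111
  - - 0.0
    - 2.145012375621
    - -0.038959238322
    - -0.140068494579
    - -0.203774909823
    - 0.77651867651
    - 0.471096785424
    - 0.0
    - 0.0
  - - 2.259201374978
    - 0.762008634577
    - -0.779801353539
    - -0.39320740345
    - 0.617157361057
    - 0.0
    - 1.401727973561
    - 0.911387806445
    - 0.0
  - - 1.039918386295
    - -0.399704502285
    - -1.14538645999
    - 0.29770167432
    - 1.149142480247
    - 1.787149860094
    - 0.634430108621
    - 0.991387801892
    - 0.0
  - - 1.568826583219
    - -1.188947773796
    - -1.022478273567
    - 0.611013525565
    - 1.56253779005
    - 0.0
    - 0.460038753521
    - 0.0
    - 0.0
  - - 0.221514973264
    - -1.376518801489
    - 0.060259849414
    - 2.294525508975
    - 1.636611861025
    - 1.93814700425
    - 0.0
    - 1.142384946049
    - 0.0
  - - -0.41729807181
    - -1.098004118225
    - 1.956237710311
    - 2.36595407782
    - 1.708040429871
    - 1.49874994933
    - 0.605541393342
    - 1.213813514894
    - 0.0
  - - -0.504901617428
    - -0.015222851143
    - 1.688730988763
    - 1.924093969128
    - 1.777005944945
    - 0.0
    - 1.773119197084
    - 0.0
    - 0.0
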