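11
toy_enone_synthetic opt_neutral (idealized synthetic geometry)
C     -0.670000000000     1.160474041071     0.000000000000
C      0.000000000000     0.000000000000     0.000000000000
C      1.490000000000     0.000000000000     0.000000000000
O      2.118346451390     1.045744106857     0.000000000000
C      2.170985749609    -1.336509786283     0.000000000000
H     -0.130000000000     2.095781477158     0.000000000000
H     -1.750000000000     1.160474041071     0.000000000000
H     -0.540000000000    -0.935307436087     0.000000000000
H      3.252104406962    -1.194246406511     0.000000000000
H      1.878346092936    -1.894211228962     0.890161531788
H      1.878346092936    -1.894211228962    -0.890161531788
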