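benzene
 OpenBabel09232611213D

 12 12  0  0  0  0  0  0  0  0999 V2000
    1.3831   -0.2214    0.0054 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5069   -1.3065   -0.0079 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8709   -1.0905   -0.0147 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3729    0.2110   -0.0044 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4967    1.2961    0.0106 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8812    1.0800    0.0137 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4568   -0.3898    0.0092 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8979   -2.3206   -0.0132 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5535   -1.9359   -0.0274 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4465    0.3793   -0.0083 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8878    2.3100    0.0197 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5638    1.9255    0.0230 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  6  2  0  0  0  0
  1  7  1  0  0  0  0
  2  3  2  0  0  0  0
  2  8  1  0  0  0  0
  3  4  1  0  0  0  0
  3  9  1  0  0  0  0
  4  5  2  0  0  0  0
  4 10  1  0  0  0  0
  5  6  1  0  0  0  0
  5 11  1  0  0  0  0
  6 12  1  0  0  0  0
M  END
$$$$
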