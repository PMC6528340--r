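n-butane
 OpenBabel09232611213D

 14 13  0  0  0  0  0  0  0  0999 V2000
    1.0422    0.0380   -0.0800 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5612    0.0285   -0.0717 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.1056   -1.0608    0.8503 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.6251   -1.0691    0.8598 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6705    0.8237   -0.7450 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6461    0.2264    0.9233 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6462   -0.9205   -0.4313 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9267    1.0094    0.2539 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9268   -0.1308   -1.0930 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7412   -2.0418    0.5237 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7390   -0.9023    1.8712 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.0216   -1.2564   -0.1431 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.9963   -1.8549    1.5250 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.0192   -0.1105    1.2120 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  5  1  0  0  0  0
  1  6  1  0  0  0  0
  1  7  1  0  0  0  0
  2  3  1  0  0  0  0
  2  8  1  0  0  0  0
  2  9  1  0  0  0  0
  3  4  1  0  0  0  0
  3 10  1  0  0  0  0
  3 11  1  0  0  0  0
  4 12  1  0  0  0  0
  4 13  1  0  0  0  0
  4 14  1  0  0  0  0
M  END
$$$$
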