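biphenyl
 OpenBabel09232611213D

 22 23  0  0  0  0  0  0  0  0999 V2000
    1.3534   -0.2369   -0.0304 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4865   -1.3317    0.0769 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.8881   -1.1317    0.1054 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3952    0.1597    0.0249 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5257    1.2505   -0.0989 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8725    1.0827   -0.1306 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7948    2.2413   -0.2725 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4611    3.5195    0.2137 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3231    4.6126    0.0676 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.5556    4.4506   -0.5575 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.9185    3.1999   -1.0418 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0464    2.1133   -0.9078 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4220   -0.4378   -0.0248 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8921   -2.3383    0.1395 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5625   -1.9796    0.1898 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4694    0.3254    0.0505 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9670    2.2405   -0.1852 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5180    3.6869    0.7292 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.0303    5.5883    0.4461 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.2285    5.2964   -0.6667 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8799    3.0641   -1.5311 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3602    1.1604   -1.3254 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  6  2  0  0  0  0
  1 13  1  0  0  0  0
  2  3  2  0  0  0  0
  2 14  1  0  0  0  0
  3  4  1  0  0  0  0
  3 15  1  0  0  0  0
  4  5  2  0  0  0  0
  4 16  1  0  0  0  0
  5  6  1  0  0  0  0
  5 17  1  0  0  0  0
  6  7  1  0  0  0  0
  7  8  1  0  0  0  0
  7 12  2  0  0  0  0
  8  9  2  0  0  0  0
  8 18  1  0  0  0  0
  9 10  1  0  0  0  0
  9 19  1  0  0  0  0
 10 11  2  0  0  0  0
 10 20  1  0  0  0  0
 11 12  1  0  0  0  0
 11 21  1  0  0  0  0
 12 22  1  0  0  0  0
M  END
$$$$
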