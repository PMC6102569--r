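g2
 OpenBabel09302604013D

 50 52  0  0  1  0  0  0  0  0999 V2000
    3.2928    0.4180   -0.9029 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.6214    0.7334    0.3869 C   0  0  3  0  0  0  0  0  0  0  0  0
    1.1078    0.5362    0.1794 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1799    0.8508    1.3275 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.0804    2.1391    1.8650 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9124    2.4302    2.8030 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8030    1.4374    3.2150 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6658    0.1378    2.7420 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6851   -0.1510    1.7975 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.2026   -0.1768    1.5011 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5064   -0.9956    2.1005 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.5341   -0.0177    1.8513 N   0  0  0  0  0  0  0  0  0  0  0  0
    5.5477    0.7784    1.1780 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.7234   -0.1777    1.1041 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.6680   -0.9072    2.4421 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.1775   -0.9071    2.8364 C   0  0  3  0  0  0  0  0  0  0  0  0
    5.0091   -0.4057    4.2890 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.9002   -0.5153    5.1322 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.7584    0.0581    4.6193 N   0  0  0  0  0  0  0  0  0  0  0  0
    3.5006    0.6413    5.9099 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0565    0.5488    6.3004 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.6536   -0.2778    7.3531 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3136   -0.3069    7.7057 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6338    0.4407    7.1092 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.2185    1.2340    6.1011 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.0872    1.3051    5.6451 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8498    0.9504   -1.6508 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.1239   -0.5653   -1.1239 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8343    1.7732    0.6597 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9248   -0.4951   -0.1524 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7787    1.1709   -0.6564 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7475    2.9327    1.5395 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9922    3.4310    3.2200 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.5812    1.6626    3.9407 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.3227   -0.6491    3.1039 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6069   -1.1683    1.4185 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.7757    1.6297    1.8295 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.2613    1.1599    0.2018 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.6746    0.3350    0.9441 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.5764   -0.8972    0.2896 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.2921   -0.3722    3.1661 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.0615   -1.9258    2.3637 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.7468   -1.9131    2.7680 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0113   -0.0178    3.9341 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8032    1.6950    5.8680 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.1343    0.1642    6.6656 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.3687   -0.8836    7.8988 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0406   -0.9420    8.5114 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9941    1.8483    5.6629 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.3408    1.9472    4.8084 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1 27  1  0  0  0  0
  1 28  1  0  0  0  0
  2  3  1  0  0  0  0
  2 10  1  0  0  0  0
  2 29  1  0  0  0  0
  3  4  1  0  0  0  0
  3 30  1  0  0  0  0
  3 31  1  0  0  0  0
  4  5  1  0  0  0  0
  4  9  2  0  0  0  0
  5  6  2  0  0  0  0
  5 32  1  0  0  0  0
  6  7  1  0  0  0  0
  6 33  1  0  0  0  0
  7  8  2  0  0  0  0
  7 34  1  0  0  0  0
  8  9  1  0  0  0  0
  8 35  1  0  0  0  0
  9 36  1  0  0  0  0
 10 11  2  0  0  0  0
 10 12  1  0  0  0  0
 12 13  1  0  0  0  0
 12 16  1  0  0  0  0
 13 14  1  0  0  0  0
 13 37  1  0  0  0  0
 13 38  1  0  0  0  0
 14 15  1  0  0  0  0
 14 39  1  0  0  0  0
 14 40  1  0  0  0  0
 15 16  1  0  0  0  0
 15 41  1  0  0  0  0
 15 42  1  0  0  0  0
 16 17  1  0  0  0  0
 16 43  1  0  0  0  0
 17 18  2  0  0  0  0
 17 19  1  0  0  0  0
 19 20  1  0  0  0  0
 19 44  1  0  0  0  0
 20 21  1  0  0  0  0
 20 45  1  0  0  0  0
 20 46  1  0  0  0  0
 21 22  1  0  0  0  0
 21 26  2  0  0  0  0
 22 23  2  0  0  0  0
 22 47  1  0  0  0  0
 23 24  1  0  0  0  0
 23 48  1  0  0  0  0
 24 25  2  0  0  0  0
 25 26  1  0  0  0  0
 25 49  1  0  0  0  0
 26 50  1  0  0  0  0
M  END
$$$$
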