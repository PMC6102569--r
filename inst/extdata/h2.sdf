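h2
 OpenBabel09302604013D

 27 27  0  0  1  0  0  0  0  0999 V2000
    0.9953    0.2627   -0.1069 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.2550    0.0029    0.0193 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9034    0.2893    1.1859 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.9963   -0.5901   -1.1281 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5570   -0.3397   -2.4284 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.2351   -0.8863   -3.5209 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.3604   -1.6997   -3.3338 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.1319   -2.3351   -4.4758 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.6216   -2.0577   -5.8972 C   0  0  1  0  0  0  0  0  0  0  0  0
    4.7108   -0.6592   -6.2457 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.4481   -2.8096   -6.9403 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.9587   -3.9072   -6.7923 O   0  0  0  0  0  0  0  0  0  0  0  0
    5.5417   -2.0959   -8.0938 O   0  0  0  0  0  0  0  0  0  0  0  0
    4.7900   -1.9514   -2.0171 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.1154   -1.4000   -0.9214 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6249    0.6256    0.7723 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4472    0.9742    1.7757 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.8959    0.4820    1.0945 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6825    0.2860   -2.5958 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8522   -0.6565   -4.5123 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.1339   -3.4208   -4.3095 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.1733   -1.9940   -4.3995 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5794   -2.3700   -6.0213 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.4820   -0.2910   -5.7717 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.0712   -1.2381   -7.9598 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.6475   -2.5987   -1.8362 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.4503   -1.6377    0.0837 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  1 16  1  0  0  0  0
  2  3  1  0  0  0  0
  2  4  1  0  0  0  0
  3 17  1  0  0  0  0
  3 18  1  0  0  0  0
  4  5  1  0  0  0  0
  4 15  2  0  0  0  0
  5  6  2  0  0  0  0
  5 19  1  0  0  0  0
  6  7  1  0  0  0  0
  6 20  1  0  0  0  0
  7  8  1  0  0  0  0
  7 14  2  0  0  0  0
  8  9  1  0  0  0  0
  8 21  1  0  0  0  0
  8 22  1  0  0  0  0
  9 10  1  0  0  0  0
  9 11  1  0  0  0  0
  9 23  1  6  0  0  0
 10 24  1  0  0  0  0
 11 12  2  0  0  0  0
 11 13  1  0  0  0  0
 13 25  1  0  0  0  0
 14 15  1  0  0  0  0
 14 26  1  0  0  0  0
 15 27  1  0  0  0  0
M  END
$$$$
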