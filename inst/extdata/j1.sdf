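j1
 OpenBabel09302604013D

 32 33  0  0  0  0  0  0  0  0999 V2000
    1.1769    0.8875   -2.3881 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2049    0.2938   -3.1985 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0939    0.1204   -2.7241 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.4190    0.5226   -1.4318 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4487    1.1138   -0.6214 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8623    1.3078   -1.0879 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.8334    2.0738   -0.2168 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.2838    1.7266   -0.3791 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.2271    2.6266   -0.7226 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.6956    2.3143   -0.8155 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.2826    2.5281   -2.1912 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.3558    3.4099   -2.3920 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.9289    3.5509   -3.6583 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.4390    2.8128   -4.7344 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.3749    1.9342   -4.5485 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.8016    1.7918   -3.2847 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1768    1.0308   -2.7907 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4588   -0.0200   -4.2078 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8535   -0.3217   -3.3632 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4305    0.3898   -1.0574 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7273    1.4414    0.3782 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.5813    1.8990    0.8372 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6719    3.1420   -0.4071 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.5688    0.6970   -0.1685 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.9372    3.6571   -0.9175 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.8902    1.2755   -0.5244 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.2179    2.9406   -0.0812 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.7654    3.9828   -1.5628 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.7661    4.2277   -3.8049 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.8895    2.9189   -5.7181 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.9962    1.3514   -5.3838 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.9836    1.0881   -3.1493 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  6  2  0  0  0  0
  1 17  1  0  0  0  0
  2  3  2  0  0  0  0
  2 18  1  0  0  0  0
  3  4  1  0  0  0  0
  3 19  1  0  0  0  0
  4  5  2  0  0  0  0
  4 20  1  0  0  0  0
  5  6  1  0  0  0  0
  5 21  1  0  0  0  0
  6  7  1  0  0  0  0
  7  8  1  0  0  0  0
  7 22  1  0  0  0  0
  7 23  1  0  0  0  0
  8  9  2  0  0  0  0
  8 24  1  0  0  0  0
  9 10  1  0  0  0  0
  9 25  1  0  0  0  0
 10 11  1  0  0  0  0
 10 26  1  0  0  0  0
 10 27  1  0  0  0  0
 11 12  1  0  0  0  0
 11 16  2  0  0  0  0
 12 13  2  0  0  0  0
 12 28  1  0  0  0  0
 13 14  1  0  0  0  0
 13 29  1  0  0  0  0
 14 15  2  0  0  0  0
 14 30  1  0  0  0  0
 15 16  1  0  0  0  0
 15 31  1  0  0  0  0
 16 32  1  0  0  0  0
M  END
$$$$
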