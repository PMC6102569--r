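h1
 OpenBabel09302604013D

 26 27  0  0  1  0  0  0  0  0999 V2000
    5.9453   -2.8379    2.5919 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.7155   -1.9782    1.7856 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.4205   -0.8580    0.8832 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.0275   -1.0592   -0.4323 N   0  0  0  0  0  0  0  0  0  0  0  0
    5.6796    0.0307   -1.3483 C   0  0  1  0  0  0  0  0  0  0  0  0
    6.3343    1.3868   -0.9813 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.6936    1.4379   -1.6865 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.3879    0.6553   -2.9204 C   0  0  0  0  0  0  0  0  0  0  0  0
    8.0760    0.6757   -4.1237 C   0  0  0  0  0  0  0  0  0  0  0  0
    7.6180   -0.1381   -5.1589 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.5033   -0.9705   -4.9713 C   0  0  0  0  0  0  0  0  0  0  0  0
    5.8251   -0.9941   -3.7487 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.2720   -0.1698   -2.7254 C   0  0  0  0  0  0  0  0  0  0  0  0
    6.1513   -3.5694    3.3392 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.8175    0.0454    1.3570 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.3349   -0.7380    0.7972 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.6724   -1.9334   -0.8192 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.5912    0.1447   -1.4295 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.4369    1.5758    0.0900 H   0  0  0  0  0  0  0  0  0  0  0  0
    5.6973    2.1946   -1.3698 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.4721    0.9380   -1.1015 H   0  0  0  0  0  0  0  0  0  0  0  0
    7.9900    2.4673   -1.9060 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.9389    1.3178   -4.2636 H   0  0  0  0  0  0  0  0  0  0  0  0
    8.1299   -0.1283   -6.1180 H   0  0  0  0  0  0  0  0  0  0  0  0
    6.1634   -1.5973   -5.7925 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.9601   -1.6371   -3.6153 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  3  0  0  0  0
  1 14  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  3 15  1  0  0  0  0
  3 16  1  0  0  0  0
  4 17  1  0  0  0  0
  5  6  1  0  0  0  0
  5 13  1  0  0  0  0
  5  4  1  0  0  0  0
  5 18  1  6  0  0  0
  6  7  1  0  0  0  0
  6 19  1  0  0  0  0
  6 20  1  0  0  0  0
  7  8  1  0  0  0  0
  7 21  1  0  0  0  0
  7 22  1  0  0  0  0
  8  9  1  0  0  0  0
  8 13  2  0  0  0  0
  9 10  2  0  0  0  0
  9 23  1  0  0  0  0
 10 11  1  0  0  0  0
 10 24  1  0  0  0  0
 11 12  2  0  0  0  0
 11 25  1  0  0  0  0
 12 13  1  0  0  0  0
 12 26  1  0  0  0  0
M  END
$$$$
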