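site_id,tree_id,dbh_cm,height_m,volume_m3,source
S01,S01_t001,10.5262,10.9938,0.0532753,synthetic
S01,S01_t002,10.516,14.8717,0.0452621,synthetic
S01,S01_t003,9.42943,12.1129,0.0468757,synthetic
S01,S01_t004,6.24454,8.11396,0.0135205,synthetic
S01,S01_t005,13.0469,14.8515,0.0723855,synthetic
S01,S01_t006,8.49725,9.36886,0.0375864,synthetic
S01,S01_t007,12.4894,13.8587,0.0866693,synthetic
S01,S01_t008,8.85196,10.5028,0.0406525,synthetic
S01,S01_t009,7.63713,13.1763,0.0280598,synthetic
S01,S01_t010,8.93234,10.7677,0.0377811,synthetic
S01,S01_t011,7.55673,9.595,0.0223979,synthetic
S01,S01_t012,8.58217,8.83725,0.0327299,synthetic
S02,S02_t001,10.5018,13.744,0.0489471,synthetic
S02,S02_t002,6.7626,8.66075,0.0167457,synthetic
S02,S02_t003,6.29101,6.57961,0.0148888,synthetic
S02,S02_t004,16.4844,19.0037,0.175656,synthetic
S02,S02_t005,4.91097,5.97708,0.00659024,synthetic
S02,S02_t006,9.99856,9.43684,0.0466349,synthetic
S02,S02_t007,5.53972,6.12978,0.0112741,synthetic
S02,S02_t008,7.60925,9.76448,0.0200329,synthetic
S02,S02_t009,9.6295,10.3878,0.0384492,synthetic
S02,S02_t010,6.83439,8.58945,0.0156326,synthetic
S02,S02_t011,14.2215,13.9035,0.115762,synthetic
S02,S02_t012,13.7353,13.1633,0.094498,synthetic
S03,S03_t001,6.35315,5.50639,0.0111993,synthetic
S03,S03_t002,13.4839,11.9774,0.101989,synthetic
S03,S03_t003,6.4998,6.63595,0.0125141,synthetic
S03,S03_t004,12.2964,11.8141,0.0632895,synthetic
S03,S03_t005,6.55219,5.74382,0.0125063,synthetic
S03,S03_t006,9.23362,10.0768,0.0278653,synthetic
S03,S03_t007,7.83006,7.55126,0.0184927,synthetic
S03,S03_t008,11.6555,12.8473,0.0680889,synthetic
S03,S03_t009,6.00893,5.72162,0.0113215,synthetic
S03,S03_t010,8.87026,8.57783,0.0307529,synthetic
S03,S03_t011,12.0518,13.4059,0.0596544,synthetic
S03,S03_t012,10.5054,10.3385,0.0334907,synthetic
S04,S04_t001,13.9339,11.2154,0.113176,synthetic
S04,S04_t002,17.5436,14.6447,0.229597,synthetic
S04,S04_t003,13.83,12.1135,0.0948996,synthetic
S04,S04_t004,6.39813,5.18266,0.0122455,synthetic
S04,S04_t005,13.2176,12.154,0.0930203,synthetic
S04,S04_t006,13.4981,14.4295,0.0874267,synthetic
S04,S04_t007,10.6938,10.1553,0.043457,synthetic
S04,S04_t008,5.08905,5.14103,0.00617937,synthetic
S04,S04_t009,12.7124,14.1341,0.0721927,synthetic
S04,S04_t010,16.3149,13.2134,0.149296,synthetic
S04,S04_t011,10.3526,8.7549,0.0417476,synthetic
S04,S04_t012,17.8347,19.5011,0.185317,synthetic
S05,S05_t001,11.6127,10.8804,0.0474351,synthetic
S05,S05_t002,12.4457,11.0582,0.0678779,synthetic
S05,S05_t003,20.6705,20.4537,0.396815,synthetic
S05,S05_t004,15.2677,15.2219,0.149983,synthetic
S05,S05_t005,8.18918,7.39577,0.019305,synthetic
S05,S05_t006,9.12651,7.83905,0.0293925,synthetic
S05,S05_t007,10.4808,11.0094,0.0424454,synthetic
S05,S05_t008,18.4848,16.9325,0.266042,synthetic
S05,S05_t009,13.3321,12.6178,0.0970843,synthetic
S05,S05_t010,9.60201,7.46823,0.03764,synthetic
S05,S05_t011,7.41098,5.24947,0.0134638,synthetic
S05,S05_t012,8.70277,7.56767,0.020897,synthetic
S06,S06_t001,7.91896,6.703,0.0160653,synthetic
S06,S06_t002,7.94577,5.83014,0.0155105,synthetic
S06,S06_t003,8.62421,5.22454,0.0216591,synthetic
S06,S06_t004,8.45281,5.56159,0.016512,synthetic
S06,S06_t005,16.8608,18.048,0.164268,synthetic
S06,S06_t006,7.81481,6.18511,0.015988,synthetic
S06,S06_t007,5.3754,2.91304,0.00397781,synthetic
S06,S06_t008,23.7137,29.8977,0.654514,synthetic
S06,S06_t009,13.2061,9.70237,0.0816409,synthetic
S06,S06_t010,17.2114,22.0764,0.204988,synthetic
S06,S06_t011,6.25664,2.92761,0.00622734,synthetic
S06,S06_t012,11.4541,8.42267,0.048384,synthetic
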