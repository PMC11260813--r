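station,year,scale,r2,rmse,mae,wi
Baoding,2015,daily,0.652,1.625,1.103,0.801
Baoding,2016,daily,0.609,1.580,1.097,0.781
Baoding,2017,daily,0.670,1.774,1.191,0.778
Baoding,2018,daily,0.630,1.575,1.060,0.824
Baoding,2019,daily,0.600,1.600,1.200,0.822
Xinji,2017,daily,0.805,1.250,0.906,0.906
Xinji,2018,daily,0.743,1.267,0.910,0.894
Xinji,2019,daily,0.771,1.323,0.881,0.886
Xinji,2020,daily,0.754,1.179,1.145,0.910
Xinji,2021,daily,0.656,1.260,1.120,0.861
Handan,2015,daily,0.675,2.043,1.699,0.842
Handan,2016,daily,0.693,2.327,1.989,0.782
Handan,2017,daily,0.751,2.172,1.845,0.834
Handan,2018,daily,0.664,2.252,1.923,0.804
Handan,2019,daily,0.681,1.985,1.660,0.853
Baoding,2015,monthly,0.782,1.219,0.973,0.825
Baoding,2016,monthly,0.725,1.321,0.956,0.788
Baoding,2017,monthly,0.859,1.374,1.065,0.809
Baoding,2018,monthly,0.778,1.097,0.908,0.856
Baoding,2019,monthly,0.701,1.247,0.972,0.859
Xinji,2017,monthly,0.926,0.856,0.706,0.934
Xinji,2018,monthly,0.880,0.798,0.670,0.934
Xinji,2019,monthly,0.876,0.979,0.675,0.912
Xinji,2020,monthly,0.903,1.023,0.658,0.960
Xinji,2021,monthly,0.768,0.896,0.773,0.898
Handan,2015,monthly,0.909,1.465,1.345,0.874
Handan,2016,monthly,0.885,1.999,1.884,0.765
Handan,2017,monthly,0.943,1.807,1.727,0.832
Handan,2018,monthly,0.890,1.814,1.685,0.800
Handan,2019,monthly,0.896,1.408,1.290,0.897
Baoding,2015,dekad,0.877,1.321,1.006,0.862
Baoding,2016,dekad,0.849,1.363,0.991,0.823
Baoding,2017,dekad,0.812,1.465,1.085,0.837
Baoding,2018,dekad,0.727,1.211,0.965,0.888
Baoding,2019,dekad,0.673,1.337,1.065,0.887
Xinji,2017,dekad,0.894,0.963,0.789,0.945
Xinji,2018,dekad,0.849,0.894,0.685,0.945
Xinji,2019,dekad,0.852,1.055,0.717,0.927
Xinji,2020,dekad,0.856,1.050,0.700,0.957
Xinji,2021,dekad,0.741,0.925,0.760,0.917
Handan,2015,dekad,0.810,1.677,1.490,0.778
Handan,2016,dekad,0.848,2.062,1.895,0.548
Handan,2017,dekad,0.907,1.869,1.741,0.715
Handan,2018,dekad,0.838,1.886,1.688,0.637
Handan,2019,dekad,0.856,1.492,1.345,0.837
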