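station,year_type,model,r2,rmse,mae,wi
Baoding,high flow year,PT,0.637,1.886,1.554,0.670
Baoding,high flow year,HA,0.600,5.222,4.226,0.485
Baoding,high flow year,MC,0.359,2.115,1.714,0.731
Baoding,high flow year,FR,0.685,1.227,0.891,0.853
Baoding,median water year,PT,0.755,2.483,1.839,0.680
Baoding,median water year,HA,0.747,4.965,4.050,0.661
Baoding,median water year,MC,0.566,2.056,1.649,0.856
Baoding,median water year,FR,0.799,1.626,1.103,0.867
Baoding,low flow year,PT,0.695,2.161,1.606,0.698
Baoding,low flow year,HA,0.715,5.249,4.293,0.598
Baoding,low flow year,MC,0.486,2.105,1.577,0.819
Baoding,low flow year,FR,0.724,1.441,0.990,0.867
Baoding,special dry year,PT,0.754,2.721,2.052,0.669
Baoding,special dry year,HA,0.751,4.978,4.036,0.675
Baoding,special dry year,MC,0.591,2.231,1.736,0.859
Baoding,special dry year,FR,0.784,1.876,1.277,0.837
Xinji,high flow year,PT,0.659,2.082,1.659,0.698
Xinji,high flow year,HA,0.660,5.178,4.225,0.551
Xinji,high flow year,MC,0.415,2.073,1.668,0.774
Xinji,high flow year,FR,0.707,1.312,0.958,0.874
Xinji,median water year,PT,0.722,2.099,1.705,0.691
Xinji,median water year,HA,0.711,4.929,3.945,0.587
Xinji,median water year,MC,0.500,2.262,1.792,0.795
Xinji,median water year,FR,0.753,1.356,0.975,0.868
Xinji,low flow year,PT,0.727,1.899,1.424,0.738
Xinji,low flow year,HA,0.749,5.334,4.454,0.573
Xinji,low flow year,MC,0.496,1.979,1.530,0.819
Xinji,low flow year,FR,0.768,1.166,0.787,0.908
Xinji,special dry year,PT,0.719,2.174,1.665,0.700
Xinji,special dry year,HA,0.751,5.093,4.208,0.605
Xinji,special dry year,MC,0.511,2.052,1.600,0.827
Xinji,special dry year,FR,0.757,1.384,0.935,0.880
Handan,high flow year,PT,0.626,2.385,1.784,0.672
Handan,high flow year,HA,0.649,5.045,4.068,0.607
Handan,high flow year,MC,0.455,2.107,1.666,0.803
Handan,high flow year,FR,0.606,2.856,2.515,0.723
Handan,median water year,PT,0.612,2.611,1.957,0.632
Handan,median water year,HA,0.663,5.211,4.235,0.611
Handan,median water year,MC,0.553,2.028,1.633,0.848
Handan,median water year,FR,0.585,2.373,1.990,0.781
Handan,low flow year,PT,0.597,2.922,2.186,0.601
Handan,low flow year,HA,0.623,4.739,3.803,0.651
Handan,low flow year,MC,0.329,2.624,2.032,0.741
Handan,low flow year,FR,0.632,2.151,1.820,0.821
Handan,special dry year,PT,0.742,2.473,1.931,0.684
Handan,special dry year,HA,0.719,5.181,4.223,0.631
Handan,special dry year,MC,0.547,2.259,1.746,0.836
Handan,special dry year,FR,0.751,2.172,1.840,0.834
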