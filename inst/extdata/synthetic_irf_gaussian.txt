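# synthetic Gaussian instrument response, FWHM 0.31 ns
# columns: time_ns intensity
-1.2 2.74474e-18
-1.18 1.08373e-17
-1.16 4.18139e-17
-1.14 1.5765e-16
-1.12 5.80823e-16
-1.1 2.09108e-15
-1.08 7.35651e-15
-1.06 2.52901e-14
-1.04 8.49581e-14
-1.02 2.78891e-13
-1 8.94626e-13
-0.98 2.8043e-12
-0.96 8.5898e-12
-0.94 2.57109e-11
-0.92 7.52019e-11
-0.9 2.14939e-10
-0.88 6.00315e-10
-0.86 1.63839e-09
-0.84 4.36952e-09
-0.82 1.13874e-08
-0.8 2.89997e-08
-0.78 7.21666e-08
-0.76 1.75492e-07
-0.74 4.17016e-07
-0.72 9.68332e-07
-0.7 2.19721e-06
-0.68 4.87188e-06
-0.66 1.05559e-05
-0.64 2.23498e-05
-0.62 4.62409e-05
-0.6 9.34878e-05
-0.58 0.000184697
-0.56 0.000356567
-0.54 0.000672663
-0.52 0.00124003
-0.5 0.00223378
-0.48 0.00393211
-0.46 0.00676374
-0.44 0.0113691
-0.42 0.018674
-0.4 0.0299728
-0.38 0.0470104
-0.36 0.0720503
-0.34 0.107908
-0.32 0.157924
-0.3 0.225849
-0.28 0.31562
-0.26 0.43101
-0.24 0.575156
-0.22 0.749999
-0.2 0.955678
-0.18 1.18998
-0.16 1.44791
-0.14 1.72155
-0.12 2.00021
-0.1 2.27095
-0.08 2.5195
-0.06 2.73148
-0.04 2.89373
-0.02 2.99567
0 3.03044
0.02 2.99567
0.04 2.89373
0.06 2.73148
0.08 2.5195
0.1 2.27095
0.12 2.00021
0.14 1.72155
0.16 1.44791
0.18 1.18998
0.2 0.955678
0.22 0.749999
0.24 0.575156
0.26 0.43101
0.28 0.31562
0.3 0.225849
0.32 0.157924
0.34 0.107908
0.36 0.0720503
0.38 0.0470104
0.4 0.0299728
0.42 0.018674
0.44 0.0113691
0.46 0.00676374
0.48 0.00393211
0.5 0.00223378
0.52 0.00124003
0.54 0.000672663
0.56 0.000356567
0.58 0.000184697
0.6 9.34878e-05
0.62 4.62409e-05
0.64 2.23498e-05
0.66 1.05559e-05
0.68 4.87188e-06
0.7 2.19721e-06
0.72 9.68332e-07
0.74 4.17016e-07
0.76 1.75492e-07
0.78 7.21666e-08
0.8 2.89997e-08
0.82 1.13874e-08
0.84 4.36952e-09
0.86 1.63839e-09
0.88 6.00315e-10
0.9 2.14939e-10
0.92 7.52019e-11
0.94 2.57109e-11
0.96 8.5898e-12
0.98 2.8043e-12
1 8.94626e-13
1.02 2.78891e-13
1.04 8.49581e-14
1.06 2.52901e-14
1.08 7.35651e-15
1.1 2.09108e-15
1.12 5.80823e-16
1.14 1.5765e-16
1.16 4.18139e-17
1.18 1.08373e-17
1.2 2.74474e-18
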