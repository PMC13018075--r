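age,sex,weight_median,weight_cv,height_median,height_cv
3,M,13.717,0.13,97.652,0.04
3.5,M,14.157,0.13,99.65,0.04
4,M,14.664,0.13,101.711,0.04
4.5,M,15.249,0.13,103.833,0.04
5,M,15.92,0.13,106.011,0.04
5.5,M,16.689,0.13,108.244,0.04
6,M,17.567,0.13,110.527,0.04
6.5,M,18.566,0.13,112.856,0.04
7,M,19.697,0.13,115.225,0.04
7.5,M,20.972,0.13,117.631,0.04
8,M,22.402,0.13,120.067,0.04
8.5,M,23.997,0.13,122.529,0.04
9,M,25.762,0.13,125.008,0.04
9.5,M,27.703,0.13,127.501,0.04
10,M,29.818,0.13,130,0.04
10.5,M,32.105,0.13,132.499,0.04
11,M,34.554,0.13,134.992,0.04
11.5,M,37.148,0.13,137.471,0.04
12,M,39.868,0.13,139.933,0.04
12.5,M,42.688,0.13,142.369,0.04
13,M,45.576,0.13,144.775,0.04
13.5,M,48.5,0.13,147.144,0.04
14,M,51.424,0.13,149.473,0.04
14.5,M,54.312,0.13,151.756,0.04
15,M,57.132,0.13,153.989,0.04
15.5,M,59.852,0.13,156.167,0.04
16,M,62.446,0.13,158.289,0.04
3,F,13.174,0.13,95.965,0.04
3.5,F,13.622,0.13,97.947,0.04
4,F,14.14,0.13,99.992,0.04
4.5,F,14.738,0.13,102.097,0.04
5,F,15.428,0.13,104.258,0.04
5.5,F,16.22,0.13,106.472,0.04
6,F,17.126,0.13,108.735,0.04
6.5,F,18.159,0.13,111.042,0.04
7,F,19.33,0.13,113.389,0.04
7.5,F,20.652,0.13,115.77,0.04
8,F,22.133,0.13,118.18,0.04
8.5,F,23.783,0.13,120.613,0.04
9,F,25.606,0.13,123.062,0.04
9.5,F,27.604,0.13,125.522,0.04
10,F,29.773,0.13,127.985,0.04
10.5,F,32.105,0.13,130.446,0.04
11,F,34.586,0.13,132.898,0.04
11.5,F,37.194,0.13,135.335,0.04
12,F,39.903,0.13,137.75,0.04
12.5,F,42.684,0.13,140.137,0.04
13,F,45.5,0.13,142.491,0.04
13.5,F,48.316,0.13,144.807,0.04
14,F,51.097,0.13,147.079,0.04
14.5,F,53.806,0.13,149.304,0.04
15,F,56.414,0.13,151.476,0.04
15.5,F,58.895,0.13,153.592,0.04
16,F,61.227,0.13,155.649,0.04
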