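age,sex,mu_ln,sd_ln
3,M,4.78749,0.4
3.5,M,4.82749,0.4
4,M,4.86749,0.4
4.5,M,4.90749,0.4
5,M,4.94749,0.4
5.5,M,4.98749,0.4
6,M,5.02749,0.4
6.5,M,5.06749,0.4
7,M,5.10749,0.4
7.5,M,5.14749,0.4
8,M,5.18749,0.4
8.5,M,5.22749,0.4
9,M,5.26749,0.4
9.5,M,5.30749,0.4
10,M,5.34749,0.4
10.5,M,5.38749,0.4
11,M,5.42749,0.4
11.5,M,5.46749,0.4
12,M,5.50749,0.4
12.5,M,5.54749,0.4
13,M,5.58749,0.4
13.5,M,5.62749,0.4
14,M,5.66749,0.4
14.5,M,5.70749,0.4
15,M,5.74749,0.4
15.5,M,5.78749,0.4
16,M,5.82749,0.4
3,F,4.86753,0.4
3.5,F,4.90753,0.4
4,F,4.94753,0.4
4.5,F,4.98753,0.4
5,F,5.02753,0.4
5.5,F,5.06753,0.4
6,F,5.10753,0.4
6.5,F,5.14753,0.4
7,F,5.18753,0.4
7.5,F,5.22753,0.4
8,F,5.26753,0.4
8.5,F,5.30753,0.4
9,F,5.34753,0.4
9.5,F,5.38753,0.4
10,F,5.42753,0.4
10.5,F,5.46753,0.4
11,F,5.50753,0.4
11.5,F,5.54753,0.4
12,F,5.58753,0.4
12.5,F,5.62753,0.4
13,F,5.66753,0.4
13.5,F,5.70753,0.4
14,F,5.74753,0.4
14.5,F,5.78753,0.4
15,F,5.82753,0.4
15.5,F,5.86753,0.4
16,F,5.90753,0.4
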