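threshold_hours,fraction_correct
0.0,0
0.1,0
0.2,0.1875
0.3,0.3125
0.4,0.3125
0.5,0.375
0.6,0.4375
0.7,0.5625
0.8,0.625
0.9,0.6875
1.0,0.6875
1.1,0.6875
1.2,0.75
1.3,0.75
1.4,0.75
1.5,0.75
1.6,0.75
1.7,0.75
1.8,0.75
1.9,0.75
2.0,0.75
2.1,0.8125
2.2,0.875
2.3,0.875
2.4,0.9375
2.5,0.9375
2.6,0.9375
2.7,0.9375
2.8,0.9375
2.9,0.9375
3.0,0.9375
3.1,0.9375
3.2,0.9375
3.3,0.9375
3.4,0.9375
3.5,0.9375
3.6,0.9375
3.7,0.9375
3.8,0.9375
3.9,0.9375
4.0,0.9375
4.1,0.9375
4.2,0.9375
4.3,0.9375
4.4,0.9375
4.5,0.9375
4.6,0.9375
4.7,0.9375
4.8,0.9375
4.9,0.9375
5.0,0.9375
5.1,0.9375
5.2,0.9375
5.3,0.9375
5.4,0.9375
5.5,0.9375
5.6,0.9375
5.7,0.9375
5.8,0.9375
5.9,0.9375
6.0,0.9375
6.1,0.9375
6.2,1
6.3,1
6.4,1
6.5,1
6.6,1
6.7,1
6.8,1
6.9,1
7.0,1
7.1,1
7.2,1
7.3,1
7.4,1
7.5,1
7.6,1
7.7,1
7.8,1
7.9,1
8.0,1
8.1,1
8.2,1
8.3,1
8.4,1
8.5,1
8.6,1
8.7,1
8.8,1
8.9,1
9.0,1
9.1,1
9.2,1
9.3,1
9.4,1
9.5,1
9.6,1
9.7,1
9.8,1
9.9,1
10.0,1
10.1,1
10.2,1
10.3,1
10.4,1
10.5,1
10.6,1
10.7,1
10.8,1
10.9,1
11.0,1
11.1,1
11.2,1
11.3,1
11.4,1
11.5,1
11.6,1
11.7,1
11.8,1
11.9,1
12.0,1
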