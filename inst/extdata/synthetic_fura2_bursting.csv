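"time_min","ratio"
0.3,0.7712
0.6,0.9122
0.9,1.9515
1.2,1.9895
1.5,1.7556
1.8,1.0343
2.1,0.6504
2.4,0.7181
2.7,0.8065
3,1.1232
3.3,1.3742
3.6,1.6704
3.9,1.594
4.2,0.6485
4.5,0.6657
4.8,0.7378
5.1,0.8364
5.4,2.4374
5.7,1.5209
6,1.6294
6.3,1.4567
6.6,0.6176
6.9,0.6775
7.2,0.7503
7.5,0.8576
7.8,2.6863
8.1,1.9661
8.4,1.7101
8.7,1.3063
9,0.6355
9.3,0.7032
9.6,0.7802
9.9,0.938
10.2,1.6949
10.5,1.9902
10.8,1.7758
11.1,0.8662
11.4,0.6558
11.7,0.7247
12,0.8166
12.3,1.529
12.6,1.3442
12.9,1.6068
13.2,1.5373
13.5,0.6202
13.8,0.6799
14.1,0.7496
14.4,0.8611
14.7,2.7156
15,1.9057
15.3,1.6786
15.6,1.3417
15.9,0.6305
16.2,0.6969
16.5,0.7751
16.8,0.9315
17.1,1.7474
17.4,1.9558
17.7,1.7489
18,0.9884
18.3,0.6504
18.6,0.7181
18.9,0.8035
19.2,1.2039
19.5,1.3349
19.8,1.6448
20.1,1.5891
20.4,0.6338
20.7,0.6723
21,0.7395
21.3,0.84
21.6,2.6015
21.9,1.5125
22.2,1.6169
22.5,1.436
22.8,0.6245
23.1,0.6859
23.4,0.7593
23.7,0.8891
24,2.2443
24.3,2.0628
24.6,1.7425
24.9,1.2475
25.2,0.6406
25.5,0.7078
25.8,0.7895
26.1,0.983
26.4,1.5196
26.7,1.7922
27,1.68
27.3,0.7585
27.6,0.6582
27.9,0.7268
28.2,0.8162
28.5,1.6774
28.8,1.3536
29.1,1.6032
29.4,1.527
29.7,0.6197
30,0.673
30.3,0.7479
30.6,0.8646
30.9,2.6853
31.2,1.9233
31.5,1.6978
31.8,1.3286
32.1,0.6322
32.4,0.7006
32.7,0.7778
33,0.9354
33.3,1.7011
33.6,1.8984
33.9,1.7185
34.2,0.9653
34.5,0.6529
34.8,0.7179
35.1,0.8057
35.4,1.1064
35.7,1.3723
36,1.6606
36.3,1.6065
36.6,0.7007
36.9,0.6596
37.2,0.7323
37.5,0.8202
37.8,1.9539
38.1,1.411
38.4,1.6212
38.7,1.4935
39,0.6204
39.3,0.678
39.6,0.75
39.9,0.8661
40.2,2.5858
40.5,2.0021
40.8,1.7238
41.1,1.2743
41.4,0.6361
41.7,0.7062
42,0.7838
42.3,0.9583
42.6,1.5751
42.9,1.8267
43.2,1.693
43.5,0.927
43.8,0.6534
44.1,0.7208
44.4,0.8089
44.7,1.1602
45,1.3648
45.3,1.6494
45.6,1.5736
45.9,0.6342
46.2,0.6713
46.5,0.7433
46.8,0.8378
47.1,2.5993
47.4,1.5289
47.7,1.6101
48,1.4305
48.3,0.6254
48.6,0.69
48.9,0.7625
49.2,0.8956
49.5,2.1538
49.8,2.0857
50.1,1.7437
50.4,1.1739
50.7,0.6422
51,0.7083
51.3,0.7917
51.6,1.0169
51.9,1.4381
52.2,1.7384
52.5,1.6422
52.8,0.7022
53.1,0.6606
53.4,0.7301
53.7,0.8258
54,2.2236
54.3,1.3983
54.6,1.5916
54.9,1.4793
55.2,0.6225
55.5,0.6818
55.8,0.7546
56.1,0.8711
56.4,2.5055
56.7,2.0449
57,1.7372
57.3,1.2529
57.6,0.6409
57.9,0.7065
58.2,0.7854
58.5,0.9689
58.8,1.538
59.1,1.8403
59.4,1.7278
59.7,0.7695
60,0.6601
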