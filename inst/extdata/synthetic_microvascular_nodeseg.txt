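# SYNTHETIC microvascular network (generated by the shuttlemech package,
# isotropic-Poisson segment process, seed 20). Node/segment text dialect:
# segment block (id type from to diameter), then node block (id x y z).
28 segments
1 4 1 2 6.384
2 4 3 4 7.471
3 4 5 6 5.482
4 4 7 8 9.763
5 4 9 10 7.942
6 4 11 12 8.641
7 4 13 14 6.269
8 4 15 16 5.742
9 4 17 18 5.043
10 4 19 20 7.480
11 4 21 22 3.273
12 4 23 24 8.418
13 4 25 26 11.952
14 4 27 28 4.102
15 4 29 30 3.227
16 4 31 32 4.733
17 4 33 34 4.135
18 4 35 36 3.338
19 4 37 38 12.913
20 4 39 40 5.812
21 4 41 42 5.164
22 4 43 44 8.113
23 4 45 46 6.705
24 4 47 48 9.137
25 4 49 50 11.482
26 4 51 52 8.302
27 4 53 54 6.947
28 4 55 56 7.894
56 nodes
1 80.980 65.401 73.651
2 58.502 100.050 61.234
3 108.723 155.203 5.120
4 155.859 68.709 6.006
5 236.656 193.970 118.624
6 244.798 223.090 88.562
7 223.645 37.698 74.119
8 266.532 55.290 -20.218
9 46.022 155.910 235.496
10 -0.355 99.719 236.553
11 40.891 108.454 23.475
12 -5.516 129.040 0.699
13 100.303 119.182 220.255
14 63.494 113.728 249.826
15 93.768 222.548 -4.402
16 91.270 232.449 24.221
17 201.675 158.856 198.151
18 156.089 166.865 234.932
19 202.548 76.595 127.736
20 176.350 52.326 167.162
21 33.670 102.821 -20.462
22 -32.706 193.954 88.585
23 158.991 5.569 127.129
24 212.410 13.531 159.536
25 37.232 82.686 17.181
26 58.977 138.602 -1.481
27 119.406 106.484 131.781
28 106.644 126.912 70.407
29 69.378 201.167 29.231
30 91.696 181.295 61.003
31 16.702 101.555 116.416
32 37.834 116.281 169.424
33 42.046 151.582 224.167
34 102.585 170.555 222.602
35 211.019 186.421 42.076
36 198.709 188.057 151.299
37 79.088 143.352 124.445
38 166.896 58.830 143.057
39 -58.803 217.699 92.401
40 73.932 111.259 154.187
41 106.023 12.596 156.832
42 114.093 22.654 175.182
43 -14.965 125.657 48.188
44 53.608 116.562 87.018
45 56.776 89.567 37.233
46 75.704 48.200 66.037
47 8.821 226.158 199.019
48 25.975 250.281 248.898
49 198.321 12.401 13.831
50 255.238 50.475 16.903
51 243.432 82.239 269.593
52 252.707 173.053 201.107
53 17.172 31.700 135.248
54 14.871 -28.365 220.179
55 165.163 119.344 89.643
56 172.391 110.854 132.774
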