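channel,1,2,3,4,5,6
1,3,4.1,8.5,7.4,9,7
2,4.5,8,6.5,5.4,6.7,6.2
3,6.3,7.1,4.6,4.8,6.4,7.8
4,96.9,94.1,118.2,87.1,135.5,106.9
5,18.6,16.1,42.9,30.5,41.9,24.1
6,1.6,2,5.8,2.7,6,3.4
7,3,4,5.2,4.8,6.2,3.8
8,8,7.2,2.1,1.9,4.3,2.8
9,1,0.8,2.4,1.1,5.7,0.8
10,3.6,4.3,7.5,3.5,11.5,5.2
11,2.9,3.2,4,3.2,4.9,3.4
12,6.4,5.4,5.5,3.9,9.3,5.4
13,8.4,5.8,7.7,3.8,11,9.7
14,6.1,2,4,1.6,10.4,3.5
15,3.8,4.6,3.3,3.8,8.5,4.3
16,4.5,4.1,6.2,4.9,6.7,6.2
17,2.2,3.1,3.3,3.2,4.5,2.9
18,2.3,2.7,2.6,2.4,3.6,2.4
19,3.8,2.9,3.7,3.2,4.8,2.6
20,4.6,4.3,4.7,3.8,7.5,4.1
21,2.7,3.6,4.8,3.8,5.7,4.1
22,4.7,4.5,4.6,4.8,6.2,5.2
23,2.3,2.4,3.1,2.3,3.2,2.8
24,3.5,4.1,4.6,3.3,4.9,3.7
25,2.9,3.9,4.3,4.2,6.2,4
26,2.4,2.9,3.7,2.5,4.9,3.7
27,4.7,5.8,6.6,5.4,8.2,4.9
28,7.2,8.3,6,4.8,16.7,4.4
29,33.5,32.1,31.5,28.5,39.3,35.7
30,3.6,5.2,5,5.1,6.5,6.5
31,5.8,4.5,2.6,1.8,5.2,7
32,9.6,12.7,11.1,8.2,18,17.4
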