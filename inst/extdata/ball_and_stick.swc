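# SWC written by touchnet
1 1 0 0 0 5 -1
2 3 10 0 0 0.5 1
3 3 20 0 0 0.5 2
4 3 30 0 0 0.5 3
5 3 40 0 0 0.5 4
6 3 50 0 0 0.5 5
7 3 60 0 0 0.5 6
8 3 70 0 0 0.5 7
9 3 80 0 0 0.5 8
10 3 90 0 0 0.5 9
11 3 100 0 0 0.5 10
12 2 -10 0 0 0.5 1
13 2 -20 0 0 0.5 12
14 2 -30 0 0 0.5 13
15 2 -40 0 0 0.5 14
16 2 -50 0 0 0.5 15
17 2 -60 0 0 0.5 16
18 2 -70 0 0 0.5 17
19 2 -80 0 0 0.5 18
20 2 -90 0 0 0.5 19
21 2 -100 0 0 0.5 20
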