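chromosome	genetic_length_morgans
1	2.86
2	2.69
3	2.23
4	2.14
5	2.04
6	1.92
7	1.87
8	1.68
9	1.66
10	1.81
11	1.58
12	1.74
13	1.26
14	1.19
15	1.41
16	1.34
17	1.28
18	1.17
19	1.07
20	1.08
21	0.62
22	0.74
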