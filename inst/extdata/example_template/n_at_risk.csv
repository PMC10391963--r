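"time","os_intervention","pfs_intervention","os_control","pfs_control"
0,120,120,120,120
1,NA,NA,NA,NA
2,NA,NA,NA,NA
3,NA,NA,NA,NA
4,NA,NA,NA,NA
5,NA,NA,NA,NA
6,116,93,109,61
7,NA,NA,NA,NA
8,NA,NA,NA,NA
9,NA,NA,NA,NA
10,NA,NA,NA,NA
11,NA,NA,NA,NA
12,109,73,101,28
13,NA,NA,NA,NA
14,NA,NA,NA,NA
15,NA,NA,NA,NA
16,NA,NA,NA,NA
17,NA,NA,NA,NA
18,104,56,92,13
19,NA,NA,NA,NA
20,NA,NA,NA,NA
21,NA,NA,NA,NA
22,NA,NA,NA,NA
23,NA,NA,NA,NA
24,99,46,82,3
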