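"time","os_intervention","pfs_intervention","os_control","pfs_control"
0,1,1,1,1
1,1,0.975,0.991666666666667,0.95
2,0.991666666666667,0.933333333333333,0.975,0.825
3,0.975,0.883333333333334,0.941666666666667,0.708333333333334
4,0.966666666666667,0.858333333333334,0.933333333333333,0.641666666666667
5,0.966666666666667,0.808333333333334,0.933333333333333,0.575000000000001
6,0.966666666666667,0.775,0.908333333333334,0.508333333333334
7,0.95,0.75,0.908333333333334,0.458333333333334
8,0.941666666666667,0.733333333333334,0.875,0.375
9,0.925,0.691666666666667,0.875,0.366666666666667
10,0.925,0.666666666666667,0.875,0.316666666666667
11,0.916666666666667,0.633333333333334,0.85,0.275
12,0.908333333333334,0.608333333333334,0.841666666666667,0.233333333333334
13,0.891666666666667,0.591666666666667,0.841666666666667,0.225
14,0.891666666666667,0.566666666666667,0.816666666666667,0.208333333333333
15,0.891666666666667,0.516666666666667,0.816666666666667,0.166666666666667
16,0.883333333333334,0.491666666666667,0.791666666666667,0.15
17,0.875,0.491666666666667,0.775,0.133333333333333
18,0.866666666666667,0.466666666666667,0.766666666666667,0.108333333333333
19,0.85,0.458333333333334,0.758333333333334,0.0916666666666667
20,0.841666666666667,0.450000000000001,0.758333333333334,0.075
21,0.841666666666667,0.450000000000001,0.741666666666667,0.0583333333333334
22,0.841666666666667,0.433333333333334,0.733333333333334,0.05
23,0.825,0.4,0.700000000000001,0.025
24,0.825,0.383333333333334,0.683333333333334,0.025
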