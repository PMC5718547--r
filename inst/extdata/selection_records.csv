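patient,view,observer1,observer2
1,1,recalculated,recalculated
1,2,recalculated,recalculated
1,3,recalculated,recalculated
1,4,recalculated,recalculated
1,5,recalculated,recalculated
2,1,recalculated,recalculated
2,2,recalculated,recalculated
2,3,recalculated,recalculated
2,4,recalculated,recalculated
2,5,recalculated,recalculated
3,1,recalculated,recalculated
3,2,recalculated,recalculated
3,3,recalculated,recalculated
3,4,recalculated,recalculated
3,5,recalculated,recalculated
4,1,recalculated,recalculated
4,2,recalculated,recalculated
4,3,recalculated,recalculated
4,4,recalculated,recalculated
4,5,recalculated,recalculated
5,1,recalculated,recalculated
5,2,recalculated,recalculated
5,3,recalculated,recalculated
5,4,recalculated,recalculated
5,5,recalculated,recalculated
6,1,recalculated,recalculated
6,2,recalculated,recalculated
6,3,recalculated,recalculated
6,4,recalculated,recalculated
6,5,recalculated,neither
7,1,neither,recalculated
7,2,neither,recalculated
7,3,neither,recalculated
7,4,neither,recalculated
7,5,neither,recalculated
8,1,neither,recalculated
8,2,neither,recalculated
8,3,neither,recalculated
8,4,neither,neither
8,5,neither,neither
9,1,neither,neither
9,2,neither,neither
9,3,neither,neither
9,4,neither,neither
9,5,neither,neither
10,1,neither,neither
10,2,neither,neither
10,3,neither,neither
10,4,original,recalculated
10,5,original,original
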