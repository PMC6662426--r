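"age","H"
1,0.9
2,1.7
3,2.7
4,3.7
5,4.7
6,5.5
7,6.2
8,6.8
9,7.2
10,7.6
11,7.8
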