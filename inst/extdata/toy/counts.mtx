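%%MatrixMarket matrix coordinate integer general
6 5 20
1 1 5
2 1 1
3 1 10
4 1 3
5 1 2
6 1 4
2 2 1
3 2 8
4 2 3
5 2 2
1 3 3
3 3 5
4 3 3
5 3 2
1 4 2
3 4 4
4 4 3
1 5 1
3 5 2
4 5 3
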