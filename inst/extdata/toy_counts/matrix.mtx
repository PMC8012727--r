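%%MatrixMarket matrix coordinate integer general
% toy 3-gene x 2-cell fixture
3 2 4
1 1 5
2 1 1
1 2 3
3 2 2
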