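# toy synthetic cell: soma with a short axon and one dendrite (um)
1 1 0 0 0 8 -1
2 2 40 0 0 1 1
3 2 80 0 0 1 2
4 2 120 0 0 0.8 3
5 3 -30 20 0 0.6 1
6 3 -60 40 0 0.5 5
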