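# co2a0000364.rd
# 1 trials, 3 chans, 4 samples
# 3.906000 msecs uV
# S1 obj , trial 0
# FP1 chan 0
0 FP1 0 -8.921
0 FP1 1 1.25
0 FP1 2 5.5
0 FP1 3 -2.0
# FP2 chan 1
0 FP2 0 0.5
0 FP2 1 -0.75
0 FP2 2 3.25
0 FP2 3 4.125
# CZ chan 2
0 CZ 0 10.0
0 CZ 1 -10.0
0 CZ 2 0.25
0 CZ 3 7.75
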