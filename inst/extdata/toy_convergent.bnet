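targets, factors
I1, I1
I2, I2
A, I1
B, I1 & !I2
C, A | B
D, !C
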