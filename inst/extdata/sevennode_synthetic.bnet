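# Synthetic seven-node worked example: in the all-active stable state
# (A = B = 1), target G has exactly two explanatory paths, both complex
# (each passes through the two-literal driver of E).
targets, factors
A, A
B, B
C, A | B
D, A & B
E, C & D
F, E
G, F
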