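[species]
DNA 1 low
DNA.P1 0 low
DNA.P2 0 low
P1 0 high
P2 0 high

[reactions]
DNA -> DNA + P1 : p1
DNA.P1 -> DNA.P1 + P1 : p1
P1 -> 0 : d1
DNA + P1 -> DNA.P1 : b1
DNA.P1 -> DNA + P1 : u1
DNA -> DNA + P2 : p2
DNA.P2 -> DNA.P2 + P2 : p2
P2 -> 0 : d2
DNA + P2 -> DNA.P2 : b2
DNA.P2 -> DNA + P2 : u2

[parameters]
p1 0.5 1.5
d1 0 0.05
b1 0 0.1
u1 0 0.1
p2 0.5 1.5
d2 0 0.05
b2 0 0.1
u2 0 0.1
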