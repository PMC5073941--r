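[species]
DNA_ON 0 low
DNA_OFF 1 low
mRNA 10 high

[reactions]
DNA_ON -> DNA_OFF : b
DNA_OFF -> DNA_ON : a
DNA_ON -> DNA_ON + mRNA : c

[parameters]
b 0 0.5
a 0 0.5
c 0 0.5
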