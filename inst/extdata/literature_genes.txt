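ADH1A
ADH1C
AKR1C4
ALDH3A1
CYP1A2
CYP2B6
CYP2C18
CYP2C19
CYP3A4
CYP3A7
GSTA1
RXRG
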