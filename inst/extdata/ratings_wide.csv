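participant,R1,R2,R3
P1,138,140,137
P2,142,145,143
P3,151,149,152
P4,136,139,135
P5,147,150,149
P6,144,143,146
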