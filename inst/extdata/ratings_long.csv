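participant,rater,value
P1,R1,138
P1,R2,140
P1,R3,137
P2,R1,142
P2,R2,145
P2,R3,143
P3,R1,151
P3,R2,149
P3,R3,152
P4,R1,136
P4,R2,139
P4,R3,135
P5,R1,147
P5,R2,150
P5,R3,149
P6,R1,144
P6,R2,143
P6,R3,146
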