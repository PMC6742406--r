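participant,mw_epochs,non_mw_epochs,total_epochs
P1,25,22,47
P2,15,45,60
P3,15,45,60
P4,10,30,40
P5,5,30,35
P6,15,33,48
P7,30,30,60
P8,20,25,45
P9,10,25,35
P10,15,15,30
P11,20,40,60
P12,20,35,55
P13,15,40,55
P14,20,25,45
P15,20,35,55
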