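population,a,b,c,d,e,f,g
SL,19,0,0,0,0,0,0
SN,29,0,0,0,0,0,0
SF1,0,17,0,0,0,0,0
SF2,0,12,0,0,0,0,1
SS,2,0,0,0,0,0,1
SD,18,0,1,3,0,0,0
SW,0,0,0,0,25,0,0
SI,29,0,1,0,0,0,0
SB,0,0,0,0,32,1,0
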