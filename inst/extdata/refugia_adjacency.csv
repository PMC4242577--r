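from,to,present,interglacial,glacial
Beringia,N Cascades,1,1,0
Beringia,Olympics,1,1,0
N Cascades,Olympics,0,1,1
N Cascades,S Cascades,0,1,1
Olympics,S Cascades,0,1,1
N Cascades,C Rockies,0,0,1
S Cascades,C Rockies,0,0,1
C Rockies,S Rockies,0,0,1
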