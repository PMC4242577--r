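taxon,Beringia,N Cascades,Olympics,S Cascades,C Rockies,S Rockies
lasiocarpa,1,1,0,0,0,0
piperi,0,0,1,0,0,0
aurita,1,0,0,0,0,0
scouleri,0,0,1,1,0,0
parryi_parryi,0,0,0,0,0,1
scabrella,0,1,0,1,0,0
parryi_idahoensis,0,0,0,0,1,0
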