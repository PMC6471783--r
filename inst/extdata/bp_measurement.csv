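site,pre_n,pre_pct,post_n,post_pct
Freetown,2199,87.7,3335,100
Mbale,4640,42.6,11300,96.2
Ndola,5673,98.2,5782,100
Zomba,11860,88.4,10783,94.1
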