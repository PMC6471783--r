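site,trained,pct_printed
Addis Ababa,192,36.9
Cap Haitien,189,73.5
Freetown,243,57.9
Gokak,297,87.1
Harare,405,69.9
Kampala,188,16.5
Lusaka,265,33.9
Mbale,314,59.2
Ndola,349,86.6
Zomba,305,89.2
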