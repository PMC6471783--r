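cluster_id,central_deliveries_mean,peripheral_deliveries_mean,home_deliveries_mean,caesarean_pct
Addis Ababa,1114,657,,22
Cap Haitien,682,0,63,20
Freetown,704,403,84,14
Gokak,952,188,4,31
Harare,1026,785,108,22
Kampala,2223,4168,,22
Lusaka,2231,3507,436,9
Mbale,1442,1583,,12
Ndola,500,797,46,10
Zomba,2705,318,86,14
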