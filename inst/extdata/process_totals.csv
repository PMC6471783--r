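metric,stage,numerator,denominator
bp_measurement,pre,6093,7693
bp_measurement,post,7800,7992
referral,pre,2784,74828
referral,post,3212,73371
caesarean,all,91158,536223
devices_missing,all,23,3868
devices_broken,all,180,3868
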