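name,geometric_volume_mL,etco2_increase_pct,etco2_increase_sd_pct,resistance_insp,resistance_exp
ANA-50,50,49,7,0,0
MIRUS,100,78,13,0,0
ANA-100,100,100,11,0,0
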