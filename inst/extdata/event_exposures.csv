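arm,event_type,events,patients,exposure_months,source
osia,soft_tissue_complication,3,80,786,pooled 6-month safety follow-up of both active-system studies
osia,reoperation,1,80,786,single explantation at day 55 post-surgery
baha,soft_tissue_complication,4,54,324,6-month safety follow-up
baha,reoperation,4,54,1296,24-month extension follow-up
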