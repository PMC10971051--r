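arm,revisions,explantations,reimplantations,source
osia,0,1,0,the single reoperation was an explantation
baha,0,2,2,two explantations and two conversions to a percutaneous device
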