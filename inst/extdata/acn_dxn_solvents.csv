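"label","fraction_acn","dielectric_constant","inverse_viscosity_P","temperature_K","excitation_nm","emission_nm"
"100% ACN + 0% DXN",1.0,36.0,290.4,298.15,379,456
"80% ACN + 20% DXN",0.8,28.6,287.1,298.15,375,450
"60% ACN + 40% DXN",0.6,22.0,243.9,298.15,375,447
"40% ACN + 60% DXN",0.4,15.3,188.1,298.15,375,443
"20% ACN + 80% DXN",0.2,8.1,129.5,298.15,375,440
"0% ACN + 100% DXN",0.0,2.1,84.8,298.15,380,420.5
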