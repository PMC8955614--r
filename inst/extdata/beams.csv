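ion,Z,energy_MeV_n,LET_keV_um,range_cm
H,1,1000,0.22,322
He,2,250,1.56,37.6
C,6,290,12.9,16.4
O,8,325,21.5,14.6
Si,14,300,68.9,7.3
Fe,26,1000,149.2,27.4
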