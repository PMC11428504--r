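compound,first_site,product,spin,phase,second_step_cost
Pt-3-O-glc,4'-OH,benzodioxole,singlet,gas,44.4
Pt-3-O-glc,4'-OH,benzodioxole,singlet,water,48.3
Pt-3-O-glc,4'-OH,benzodioxole,singlet,ethanol,47.4
Pt-3-O-glc,4'-OH,o-quinone,singlet,gas,80.8
Pt-3-O-glc,4'-OH,o-quinone,singlet,water,75.9
Pt-3-O-glc,4'-OH,o-quinone,singlet,ethanol,74.9
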