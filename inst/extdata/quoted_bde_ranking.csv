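compound,site,phase,bde
Pt-3-O-glc,4'-OH,gas,86.2
Dp-3-O-glc,4'-OH,gas,86.7
Mv-3-O-glc,4'-OH,gas,87.4
Cy-3-O-glc,4'-OH,gas,89.8
Pn-3-O-glc,4'-OH,gas,93.4
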