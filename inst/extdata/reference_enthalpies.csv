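phase,h_hydrogen_atom,h_proton,h_electron,provenance
gas,-311.100,1.478,0.752,gas-phase H-atom enthalpy (electronic + translational thermal terms) with proton/electron ideal-gas enthalpies; composite C calibrated to the bundled descriptor table (313.33 kcal/mol)
water,-312.300,-222.730,-35.600,hydration-corrected values; proton/electron split nominal; composite C calibrated to the bundled descriptor table (53.97 kcal/mol)
ethanol,-312.400,-227.880,-37.500,ethanol-solvation-corrected values; proton/electron split nominal; composite C calibrated to the bundled descriptor table (47.02 kcal/mol)
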