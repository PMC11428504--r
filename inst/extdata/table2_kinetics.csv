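reaction,site,phase,temperature,delta_g_reaction,delta_g_activation,k_ref
Pt-3-O-glc-3'-OH + .OH,3'-OH,gas,298.15,-22.7,9.8,7.45e7
Pt-3-O-glc-4'-OH + .OH,4'-OH,gas,298.15,-31.1,7.6,5.72e9
Pt-3-O-glc-5-OH + .OH,5-OH,gas,298.15,-24.0,8.1,1.33e9
Pt-3-O-glc-7-OH + .OH,7-OH,gas,298.15,-21.2,8.3,9.31e8
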