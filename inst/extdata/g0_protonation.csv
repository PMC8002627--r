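ligand_id,charge,exp_dg,exp_unc,dg_top
G0_2plus,2,-14.67,0.10,-35.93
G0_1plus,1,-14.67,0.10,-18.25
G0_neutral,0,-14.67,0.10,-4.06
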