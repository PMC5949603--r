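source,V0_uL,inj_uL,n_inj,syringe_mM,cell_uM,temp_C,KD_uM_reported,KD_uM_reported_28c
ITC protocol,200,2.5,15,0.7,50,25,0.80,6.8
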