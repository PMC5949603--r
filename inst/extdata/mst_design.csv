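source,protein_nM,top_uM,factor,levels,mix,final_top_uM,final_bottom_nM,KD_uM_reported
MST protocol,10,500,2,15,TRUE,250,15.3,4.5
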