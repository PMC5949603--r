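id,source,notation,n_methyl_positions,printed_formula,printed_mz_MH
30,Table 4,Me-l1 G k2 f P E1 a2,1,C37H54N8O8,739.41
31,Table 4,l1 Me-G k2 f P E1 a2,2,C37H54N8O8,739.41
32,Table 4,l1 G k2 Me-f P E1 a2,4,C37H54N8O9,739.41
33,Table 4,Me-l1 Me-G k2 f P E1 a2,1;2,C38H56N8O8,753.43
34,Table 4,Me-l1 G k2 Me-f P E1 a2,1;4,C38H56N8O8,753.43
35,Table 4,l1 Me-G k2 Me-f P E1 a2,2;4,C38H56N8O8,753.43
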