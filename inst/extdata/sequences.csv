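id,source,notation,c_term,thioether,printed_formula,formula_consistent,printed_adduct,printed_mz,mz_consistent
1,Table 1,l1 G k2 f P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
2,Table 1,l1 G k2 f P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
3,Table 1,l1 G k2 F P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
4,Table 1,L1 G k2 f P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
5,Table 1,l1 G k2 F P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
6,Table 1,L1 G k2 f P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
7,Table 1,L1 G k2 F P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
8,Table 1,L1 G k2 F P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
9,Table 1,L1 G K2 F P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+H]+,725.40,TRUE
10,Table 1,l1 G k2 y P E1 a2,acid,FALSE,C36H52N8O9,TRUE,[M+H]+,741.39,TRUE
11,Table 1,l1 G k2 y P E1 A2,acid,FALSE,C36H52N8O8,FALSE,[M+H]+,741.39,TRUE
12,Table 1,l1 G k2 Y P E1 a2,acid,FALSE,C36H52N8O8,FALSE,[M+H]+,741.39,TRUE
13,Table 1,L1 G k2 y P E1 a2,acid,FALSE,C36H52N8O8,FALSE,[M+H]+,741.39,TRUE
14,Table 1,l1 G k2 Y P E1 A2,acid,FALSE,C36H52N8O8,FALSE,[M+H]+,741.39,TRUE
15,Table 1,L1 G k2 y P E1 A2,acid,FALSE,C36H52N8O9,TRUE,[M+H]+,741.39,TRUE
16,Table 1,L1 G k2 Y P E1 a2,acid,FALSE,C36H52N8O8,FALSE,[M+H]+,741.39,TRUE
17,Table 1,L1 G k2 Y P E1 A2,acid,FALSE,C36H52N8O8,FALSE,[M+H]+,741.39,TRUE
18,Table 1,L1 G K2 Y P E1 A2,acid,FALSE,C36H52N8O8,FALSE,[M+H]+,741.39,TRUE
19,Table 1,k1 G k2 f P E1 a2,acid,FALSE,C36H53N9O8,TRUE,[M+H]+,740.41,TRUE
20,Table 1,l1 S k2 f P E1 a2,acid,FALSE,C37H54N8O9,TRUE,[M+H]+,755.41,TRUE
21,Table 1,l1 G k2 f K E1 a2,acid,FALSE,C37H57N9O8,TRUE,[M+H]+,756.44,TRUE
22,Table 1,k1 G k2 e P E1 c2,acid,FALSE,C32H51N9O10S,TRUE,[M+H]+,754.36,TRUE
23,Table 1,K1 G k2 f P E1 A2,acid,FALSE,C36H53N9O8,TRUE,[M+H]+,740.41,TRUE
24,Table 1,L1 S k2 f P E1 A2,acid,FALSE,C37H54N8O9,TRUE,[M+H]+,755.41,TRUE
25,Table 1,L1 G k2 f K E1 A2,acid,FALSE,C37H57N9O8,TRUE,[M+H]+,756.44,TRUE
26,Table 1,K1 G k2 e P E1 C2,acid,FALSE,C37H53N9O9,FALSE,[M+H]+,754.36,TRUE
27c,Table 3,K2 E1 K w z2 W K1 G,amide,TRUE,C52H72N14O10S,TRUE,[M+H]+,1085.53,TRUE
27x,Table 3,K2 E1 K w z2 W K1 G B G G K(biot),amide,TRUE,C88H117N21O17S2,TRUE,[M+H]+,1804.85,TRUE
27s,Table 3,K2 E1 K w z2 W K1 G F G G K(biot),amide,TRUE,C81H113N21O16S2,TRUE,[M+H]+,1700.82,TRUE
28c,Table 3,R2 E1 R f z2 F K1 G,amide,TRUE,C48H70N16O10S,TRUE,[M+H]+,1063.52,TRUE
28x,Table 3,R2 E1 R f z2 F K1 G B G G K(biot),amide,TRUE,C84H115N23O17S2,TRUE,[M+2H]2+,892.42,FALSE
28s,Table 3,R2 E1 R f z2 F K1 G F G G K(biot),amide,TRUE,C77H111N23O16S2,TRUE,[M+2H]2+,839.91,TRUE
29c,Table 3,E2 E1 E f z2 F K1 G,amide,TRUE,C46H60N10O14S,TRUE,[M+H]+,1009.41,TRUE
29x,Table 3,E2 E1 E f z2 F K1 G B G G K(biot),amide,TRUE,C82H105N17O21S2,TRUE,[M+2H]2+,864.86,TRUE
29s,Table 3,E2 E1 E f z2 F K1 G F G G K(biot),amide,TRUE,C75H101N17O20S2,TRUE,[M+H]+,1624.69,TRUE
30,Table 4,Me-l1 G k2 f P E1 a2,acid,FALSE,C37H54N8O8,TRUE,[M+H]+,739.41,TRUE
31,Table 4,l1 Me-G k2 f P E1 a2,acid,FALSE,C37H54N8O8,TRUE,[M+H]+,739.41,TRUE
32,Table 4,l1 G k2 Me-f P E1 a2,acid,FALSE,C37H54N8O9,FALSE,[M+H]+,739.41,TRUE
33,Table 4,Me-l1 Me-G k2 f P E1 a2,acid,FALSE,C38H56N8O8,TRUE,[M+H]+,753.43,TRUE
34,Table 4,Me-l1 G k2 Me-f P E1 a2,acid,FALSE,C38H56N8O8,TRUE,[M+H]+,753.43,TRUE
35,Table 4,l1 Me-G k2 Me-f P E1 a2,acid,FALSE,C38H56N8O8,TRUE,[M+H]+,753.43,TRUE
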