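id,source,kind,notation,c_term,thioether,printed_formula,formula_consistent,adduct,mz_printed,mz_consistent
1,exp. section,bicyclic,l1 G k2 f P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
2,exp. section,bicyclic,l1 G k2 f P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
3,exp. section,bicyclic,l1 G k2 F P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
4,exp. section,bicyclic,L1 G k2 f P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
5,exp. section,bicyclic,l1 G k2 F P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
6,exp. section,bicyclic,L1 G k2 f P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
7,exp. section,bicyclic,L1 G k2 F P E1 a2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
8,exp. section,bicyclic,L1 G k2 F P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
9,exp. section,bicyclic,L1 G K2 F P E1 A2,acid,FALSE,C36H52N8O8,TRUE,[M+Na]+,747.38,TRUE
10,exp. section,bicyclic,l1 G k2 y P E1 a2,acid,FALSE,C36H52N8O9,TRUE,[M+Na]+,763.37,TRUE
10,exp. section,bicyclic,l1 G k2 y P E1 a2,acid,FALSE,C36H52N8O9,TRUE,[M+K]+,779.35,TRUE
10,exp. section,bicyclic,l1 G k2 y P E1 a2,acid,FALSE,C36H52N8O9,TRUE,[M+K+H]2+,390.17,TRUE
15,exp. section,bicyclic,L1 G k2 y P E1 A2,acid,FALSE,C36H52N8O9,TRUE,[M+Na]+,763.37,TRUE
19,exp. section,bicyclic,k1 G k2 f P E1 a2,acid,FALSE,C36H53N9O8,TRUE,[M+Na]+,762.39,TRUE
19,exp. section,bicyclic,k1 G k2 f P E1 a2,acid,FALSE,C36H53N9O8,TRUE,[M+K+H]2+,389.68,TRUE
20,exp. section,bicyclic,l1 S k2 f P E1 a2,acid,FALSE,C37H54N8O9,TRUE,[M+Na]+,777.39,TRUE
20,exp. section,bicyclic,l1 S k2 f P E1 a2,acid,FALSE,C37H54N8O9,TRUE,[M+K]+,793.36,TRUE
20,exp. section,bicyclic,l1 S k2 f P E1 a2,acid,FALSE,C37H54N8O9,TRUE,[M+K+H]2+,397.18,TRUE
20,exp. section,bicyclic,l1 S k2 f P E1 a2,acid,FALSE,C37H54N8O9,TRUE,[M+Na+H]2+,389.19,TRUE
21,exp. section,bicyclic,l1 G k2 f K E1 a2,acid,FALSE,C37H57N9O8,TRUE,[M+Na]+,778.42,TRUE
22,exp. section,bicyclic,k1 G k2 e P E1 c2,acid,FALSE,C32H51N9O10S,TRUE,[M+Na]+,776.34,TRUE
22,exp. section,bicyclic,k1 G k2 e P E1 c2,acid,FALSE,C32H51N9O10S,TRUE,[M+K+H]2+,396.65,TRUE
23,exp. section,bicyclic,K1 G k2 f P E1 A2,acid,FALSE,C36H53N9O8,TRUE,[M+2H]2+,370.71,TRUE
24,exp. section,bicyclic,L1 S k2 f P E1 A2,acid,FALSE,C37H54N8O9,TRUE,[M+Na]+,777.39,TRUE
25,exp. section,bicyclic,L1 G k2 f K E1 A2,acid,FALSE,C37H57N9O8,TRUE,[M+Na]+,778.42,TRUE
35,exp. section,bicyclic,l1 Me-G k2 Me-f P E1 a2,acid,FALSE,C38H56N8O8,TRUE,[M+Na]+,775.41,TRUE
1-mono,exp. section,monocyclic,l1 G k f P E1 a,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
2-mono,exp. section,monocyclic,l1 G k f P E1 A,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
3-mono,exp. section,monocyclic,l1 G k F P E1 a,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
4-mono,exp. section,monocyclic,L1 G k f P E1 a,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
5-mono,exp. section,monocyclic,l1 G k F P E1 A,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
6-mono,exp. section,monocyclic,L1 G k f P E1 A,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
7-mono,exp. section,monocyclic,L1 G k F P E1 a,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
8-mono,exp. section,monocyclic,L1 G k F P E1 A,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
9-mono,exp. section,monocyclic,L1 G K F P E1 A,acid,FALSE,C36H54N8O9,TRUE,[M+H]+,743.41,TRUE
11-mono,exp. section,monocyclic,l1 G k y P E1 A,acid,FALSE,C36H54N8O10,TRUE,[M+H]+,759.40,TRUE
12-mono,exp. section,monocyclic,l1 G k Y P E1 a,acid,FALSE,C36H54N8O10,TRUE,[M+H]+,759.40,TRUE
13-mono,exp. section,monocyclic,L1 G k y P E1 a,acid,FALSE,C36H54N8O10,TRUE,[M+H]+,759.40,TRUE
14-mono,exp. section,monocyclic,l1 G k Y P E1 A,acid,FALSE,C36H54N8O10,TRUE,[M+H]+,759.40,TRUE
16-mono,exp. section,monocyclic,L1 G k Y P E1 a,acid,FALSE,C36H54N8O10,TRUE,[M+H]+,759.40,TRUE
17-mono,exp. section,monocyclic,L1 G k Y P E1 A,acid,FALSE,C36H54N8O10,TRUE,[M+H]+,759.40,TRUE
18-mono,exp. section,monocyclic,L1 G K Y P E1 A,acid,FALSE,C36H54N8O10,TRUE,[M+H]+,759.40,TRUE
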