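compound,source,proton,coeff,bold
1,Table 2,Leu1-HN,7.3,FALSE
2,Table 2,Leu1-HN,8.1,FALSE
3,Table 2,Leu1-HN,3.7,TRUE
4,Table 2,Leu1-HN,7.7,FALSE
5,Table 2,Leu1-HN,7.8,FALSE
6,Table 2,Leu1-HN,8.5,FALSE
7,Table 2,Leu1-HN,6.8,FALSE
8,Table 2,Leu1-HN,7.8,FALSE
9,Table 2,Leu1-HN,7.2,FALSE
1,Table 2,Gly2-HN,7.9,FALSE
2,Table 2,Gly2-HN,7.7,FALSE
3,Table 2,Gly2-HN,4.4,FALSE
4,Table 2,Gly2-HN,6.8,FALSE
5,Table 2,Gly2-HN,7.0,FALSE
6,Table 2,Gly2-HN,7.9,FALSE
7,Table 2,Gly2-HN,6.2,FALSE
8,Table 2,Gly2-HN,7.6,FALSE
9,Table 2,Gly2-HN,7.9,FALSE
1,Table 2,Lys3-HN,8.8,FALSE
2,Table 2,Lys3-HN,3.1,TRUE
3,Table 2,Lys3-HN,2.4,TRUE
4,Table 2,Lys3-HN,2.1,TRUE
5,Table 2,Lys3-HN,1.3,TRUE
6,Table 2,Lys3-HN,2.8,TRUE
7,Table 2,Lys3-HN,1.4,TRUE
8,Table 2,Lys3-HN,2.0,TRUE
9,Table 2,Lys3-HN,1.6,TRUE
1,Table 2,Phe4-HN,6.6,FALSE
2,Table 2,Phe4-HN,7.2,FALSE
3,Table 2,Phe4-HN,5.2,FALSE
4,Table 2,Phe4-HN,5.3,FALSE
5,Table 2,Phe4-HN,10.0,FALSE
6,Table 2,Phe4-HN,8.0,FALSE
7,Table 2,Phe4-HN,6.3,FALSE
8,Table 2,Phe4-HN,8.8,FALSE
9,Table 2,Phe4-HN,9.2,FALSE
1,Table 2,Glu6-HN,1.7,TRUE
2,Table 2,Glu6-HN,2.3,TRUE
3,Table 2,Glu6-HN,-1.0,TRUE
4,Table 2,Glu6-HN,1.2,TRUE
5,Table 2,Glu6-HN,1.2,TRUE
6,Table 2,Glu6-HN,1.2,TRUE
7,Table 2,Glu6-HN,1.8,TRUE
8,Table 2,Glu6-HN,1.5,TRUE
9,Table 2,Glu6-HN,7.2,FALSE
1,Table 2,Ala7-HN,3.0,TRUE
2,Table 2,Ala7-HN,7.6,FALSE
3,Table 2,Ala7-HN,0.3,TRUE
4,Table 2,Ala7-HN,1.4,TRUE
5,Table 2,Ala7-HN,9.6,FALSE
6,Table 2,Ala7-HN,6.2,FALSE
7,Table 2,Ala7-HN,9.9,FALSE
8,Table 2,Ala7-HN,9.0,FALSE
9,Table 2,Ala7-HN,8.3,FALSE
1,Table 2,Lys3-HNe,6.6,FALSE
2,Table 2,Lys3-HNe,7.3,FALSE
3,Table 2,Lys3-HNe,NA,FALSE
4,Table 2,Lys3-HNe,4.3,FALSE
5,Table 2,Lys3-HNe,6.6,FALSE
6,Table 2,Lys3-HNe,6.6,FALSE
7,Table 2,Lys3-HNe,NA,FALSE
8,Table 2,Lys3-HNe,6.5,FALSE
9,Table 2,Lys3-HNe,2.0,TRUE
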