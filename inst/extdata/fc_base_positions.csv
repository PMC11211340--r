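index,kabat,pdb,variants,conserved
1,371,351,V/I/T,FALSE
2,372,352,L/I/M,FALSE
3,373,353,P/A/G,FALSE
4,374,354,P,TRUE
5,375,355,P/S,FALSE
6,376,356,E/A/K/R/Q,FALSE
7,377,357,E/Q,FALSE
8,381,359,M/L,FALSE
9,382,360,T/S/A,FALSE
10,445,415,K/T,FALSE
11,446,416,K/S/E,FALSE
12,448,418,W,TRUE
13,449,419,V/E/Q,FALSE
14,450,420,E/K/A/Q/R,FALSE
15,451,421,R/T/G,FALSE
16,470,440,K,TRUE
17,472,442,F/I/L,FALSE
18,473,443,S,TRUE
19,474,444,R/H/L,FALSE
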