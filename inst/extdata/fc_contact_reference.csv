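condition,chain,resno,aa,class
charged,B,353,P,hydrophobic
charged,B,354,P,hydrophobic
charged,B,355,P,hydrophobic
charged,B,356,E,negative
charged,B,359,M,hydrophobic
charged,B,360,T,hydrophilic
charged,B,415,K,positive
charged,B,418,W,hydrophobic
charged,B,419,V,hydrophobic
charged,B,420,E,negative
charged,B,442,F,hydrophobic
charged,B,443,S,hydrophilic
charged,B,444,R,positive
charged,D,353,P,hydrophobic
charged,D,354,P,hydrophobic
charged,D,355,P,hydrophobic
charged,D,356,E,negative
charged,D,359,M,hydrophobic
charged,D,360,T,hydrophilic
charged,D,415,K,positive
charged,D,418,W,hydrophobic
charged,D,419,V,hydrophobic
charged,D,443,S,hydrophilic
charged,D,444,R,positive
uncharged,B,353,P,hydrophobic
uncharged,B,354,P,hydrophobic
uncharged,B,355,P,hydrophobic
uncharged,B,356,E,negative
uncharged,B,359,M,hydrophobic
uncharged,B,360,T,hydrophilic
uncharged,B,415,K,positive
uncharged,B,418,W,hydrophobic
uncharged,B,419,V,hydrophobic
uncharged,B,420,E,negative
uncharged,B,442,F,hydrophobic
uncharged,B,443,S,hydrophilic
uncharged,B,444,R,positive
uncharged,D,356,E,negative
uncharged,D,443,S,hydrophilic
uncharged,D,444,R,positive
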