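resname,donors,acceptors,rings,cations,anions,hydrophobes
ALA,1,1,0,0,0,1
ARG,6,1,0,1,0,0
ASN,3,2,0,0,0,0
ASP,1,3,0,0,1,0
CYS,1,1,0,0,0,2
GLN,3,2,0,0,0,0
GLU,1,3,0,0,1,0
GLY,1,1,0,0,0,0
HIS,2,3,1,0,0,0
ILE,1,1,0,0,0,4
LEU,1,1,0,0,0,4
LYS,4,1,0,1,0,0
MET,1,1,0,0,0,4
PHE,1,1,1,0,0,7
PRO,0,1,0,0,0,3
SER,2,2,0,0,0,0
THR,2,2,0,0,0,0
TRP,2,1,2,0,0,9
TYR,2,2,1,0,0,7
VAL,1,1,0,0,0,3
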