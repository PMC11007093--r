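label,group,side
AF_left,AF,left
AF_right,AF,right
ATR_left,ATR,left
ATR_right,ATR,right
CG_left,CG,left
CG_right,CG,right
CST_left,CST,left
CST_right,CST,right
FPT_left,FPT,left
FPT_right,FPT,right
FX_left,FX,left
FX_right,FX,right
IFO_left,IFO,left
IFO_right,IFO,right
ILF_left,ILF,left
ILF_right,ILF,right
MLF_left,MLF,left
MLF_right,MLF,right
OR_left,OR,left
OR_right,OR,right
POPT_left,POPT,left
POPT_right,POPT,right
SCP_left,SCP,left
SCP_right,SCP,right
SLF_I_left,SLF_I,left
SLF_I_right,SLF_I,right
SLF_II_left,SLF_II,left
SLF_II_right,SLF_II,right
SLF_III_left,SLF_III,left
SLF_III_right,SLF_III,right
UF_left,UF,left
UF_right,UF,right
CC_1,Rostrum_and_Genu,unpaired
CC_2,Rostrum_and_Genu,unpaired
CC_3,Anterior_Body,unpaired
CC_4,Anterior_Body,unpaired
CC_5,Posterior_Body,unpaired
CC_6,Isthmus,unpaired
CC_7,Splenium,unpaired
MCP,MCP,unpaired
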