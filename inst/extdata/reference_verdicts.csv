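material,analyte,stable,onset_day
MQ,ALB,TRUE,
MQ,ALP,FALSE,8
MQ,ALT,TRUE,
MQ,Amylas,TRUE,
MQ,AST,FALSE,10
MQ,Ca,FALSE,13
MQ,TChol,TRUE,
MQ,CK,TRUE,
MQ,CL,TRUE,
MQ,Crea,TRUE,
MQ,cHDL,TRUE,
MQ,DBil,TRUE,
MQ,cLDL,TRUE,
MQ,GGT,TRUE,
MQ,Glu,TRUE,
MQ,IP,TRUE,
MQ,Iron,TRUE,
MQ,K,TRUE,
MQ,LDH,FALSE,13
MQ,Mg,TRUE,
MQ,Na,TRUE,
MQ,TBil,FALSE,13
MQ,TP,TRUE,
MQ,Trig,TRUE,
MQ,UA,TRUE,
MQ,UN,TRUE,
UC,Ca,TRUE,
UC,CL,FALSE,8
UC,Crea,TRUE,
UC,Glu,FALSE,8
UC,IP,TRUE,
UC,K,TRUE,
UC,Mg,TRUE,
UC,Na,TRUE,
UC,UA,TRUE,
UC,microALB,TRUE,
UC,UN,TRUE,
UC,TP,TRUE,
UC,Amylas,TRUE,
LL,APO A1,TRUE,
LL,APO B,TRUE,
LL,hsCRP,TRUE,
LI,Hapt,TRUE,
LI,Trf,FALSE,18
LI,CRP,TRUE,
LI,preALB,TRUE,
LI,C4,TRUE,
LI,C3,TRUE,
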