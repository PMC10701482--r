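analyte,matrix,cva,cvb,cvb_source
ALB,serum,1.9,2.6,EFLM
ALT,serum,1.5,10.1,EFLM
ALP,serum,2.3,5.3,EFLM
Amylas,serum,1.1,6.6,EFLM
APO A1,serum,2.9,5.4,EFLM
APO B,serum,4.2,7.4,EFLM
AST,serum,2.3,9.6,EFLM
C3,serum,2.9,4.6,EFLM
C4,serum,1.7,6.9,EFLM
Ca,serum,2.3,2.1,Ricos
TChol,serum,1.3,5.3,EFLM
CK,serum,1.8,15,EFLM
CL,serum,1.3,1.1,EFLM
Crea,serum,2.2,4.5,EFLM
cHDL,serum,3.1,5.8,EFLM
DBil,serum,2.8,36.8,Ricos
cLDL,serum,1.6,8.3,EFLM
GGT,serum,2.7,9.1,EFLM
Glu,serum,0.9,5,EFLM
Hapt,serum,2.3,8.6,EFLM
hsCRP,serum,11.9,58.9,EFLM
IP,serum,1.6,7.8,EFLM
Iron,serum,1,26.5,Ricos
K,serum,0.7,4.1,EFLM
LDH,serum,2.2,5.2,EFLM
Mg,serum,3.3,2.9,EFLM
Na,serum,0.5,0.5,EFLM
TBil,serum,1.7,21.8,Ricos
CRP,serum,3.7,34.1,EFLM
preALB,serum,5.5,10.9,Ricos
TP,serum,2.1,2.6,EFLM
Trig,serum,1.6,20,EFLM
Trf,serum,2.8,3.9,EFLM
UA,serum,0.8,8.6,Ricos
UN,serum,1.7,13.9,EFLM
ALB,urine,8.4,,none
Amylas,urine,2.1,94,Ricos
Ca,urine,3,27.5,Ricos
CL,urine,1.4,,none
Crea,urine,1.5,24,EFLM
Glu,urine,1.6,,none
IP,urine,2.1,18,Ricos
K,urine,1.8,24.4,Ricos
Mg,urine,5,38.3,Ricos
microALB,urine,7.9,36,EFLM
Na,urine,1.8,28.7,Ricos
TP,urine,2,35.5,Ricos
UA,urine,2.3,16.8,Ricos
UN,urine,3.4,17.4,Ricos
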