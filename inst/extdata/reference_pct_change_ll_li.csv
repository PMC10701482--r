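material,analyte,level,d1,d2,d3,d4,d5,d6,d7,d8,d9,d10,d11,d12,d13,d14,d15,d16,d17,d18,d19,d20,tcl
LL,APO A1,low,1.8,0.6,0.6,2.1,1.8,1.5,1.5,0.9,1.3,0.6,0.3,0.9,2.5,0.0,1.8,3.7,3.7,3.7,2.5,4.9,5.5
LL,APO A1,high,,,,,,,,,,,,,,,,,,,,,5.5
LL,APO B,low,1.9,-2.2,-1.5,-1.9,1.9,0.8,,-3.4,4.1,6.7,6.0,3.7,4.5,4.0,4.1,3.7,1.1,1.9,2.2,4.1,7.9
LL,APO B,high,-2.5,-1.0,-1.7,-1.0,1.1,-2.3,,-2.8,3.9,2.6,2.6,3.7,2.9,3.3,3.5,6.1,4.6,-2.5,5.0,5.4,7.9
LL,hsCRP,low,0,-2.1,-4.2,8.3,12,6.2,6.2,6.2,10,8.3,8.3,10,12,25,8.3,4.1,6.2,6.2,10,8.3,35
LL,hsCRP,high,-2.4,-1.2,-1.8,10.3,9.70,6.67,9.70,6.67,7.27,6.06,8.48,6.06,4.24,6.67,7.88,3.64,5.45,5.45,4.85,7.27,35
LI,Hapt,low,0,-0.9,-1.4,-0.9,-0.5,0.5,0.5,-0.9,2.1,0.9,-0.5,-0.5,-0.5,0.9,0.9,-1.4,-3.8,-2.3,2.8,2.3,5.8
LI,Hapt,high,0.2,-0.9,-1.1,-1.5,-0.9,-0.2,0.4,-1.8,4.0,3.8,3.1,2,3.8,2.0,3.6,2.9,0.2,-0.6,5.8,6.2*,5.8
LI,Trf,low,-0.2,0,-0.9,0.4,0.4,1.1,1.5,-1.3,-0.6,-0.9,-0.4,-0.2,1.1,-2.6,-2.2,-1.7,-2.2,-7.8*,-7.8*,-8.1*,5.3
LI,Trf,high,0.8,1.4,1.4,0.0,1.1,2.7,2.9,0.3,0.3,0.4,0.1,0.8,1.9,-1.1,0.8,-0.4,-0.8,-5.2,-5.9*,-7.4*,5.3
LI,CRP,low,3.6,1.6,2.6,2.1,3.6,1.6,4.7,4.2,2.6,1.6,3.1,-0.5,2.3,0.5,0.5,1.6,0.5,1.6,2.6,4.7,18
LI,CRP,high,2,3.3,2.6,1.1,2.5,3.7,3.6,2.7,1.9,0.9,1.9,0.3,2.7,1.4,-1.2,1.1,0.1,1.2,1.3,2.3,18
LI,preALB,low,-1.0,-0.8,-1.3,-2.9,-3.6,-4.2,2.6,-1.0,3.7,-1.3,-0.5,-1.0,1.3,1.6,-2.0,-1.6,1.3,0.5,-0.8,-2.8,11
LI,preALB,high,-0.3,0.1,-0.6,0,-2,-0.3,0.1,-0.7,1.5,-1,-1,-0.1,-0.3,0.6,-0.3,-0.6,1.3,0.7,-0.6,-1.8,11
LI,C4,low,1.2,1.6,1.2,0.9,0.7,0.7,1.8,1.2,1.3,2.3,0.5,1.8,2.1,0.7,-2.3,-0.2,-1.1,-0.4,-0.5,2.3,6.7
LI,C4,high,0.4,1.9,1.2,1.3,1.9,3.3,2.3,1.0,2.3,1.4,1.3,1.9,3.2,-1.2,-1.4,0.2,0.1,-1,1.0,0.4,6.7
LI,C3,low,-3.2,-0.4,-0.9,-0.9,-0.9,0.5,-1.4,-0.2,-1.3,-0.8,-4.5,-2.7,0.0,-5.4,-5.4,-7.2*,-5.4,-5,-4.5,-4.0,5.5
LI,C3,high,-2.4,-0.7,-0.8,-0.8,-1,1.09,-1.4,-1.8,-1.4,-0.6,-2.2,-1.4,0.27,-2.6,-5.2,-2.7,-4.1,-3.2,-2.0,-3.1,5.5
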