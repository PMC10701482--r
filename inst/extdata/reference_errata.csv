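material,analyte,level,day,printed_value,note
MQ,ALP,high,6,5.045,magnitude exceeds TCL 4.66 but cell is not marked as an exceedance while 4.666 cells in the same row are; inconsistent with any single threshold
UC,CL,low,3,-1.96,magnitude exceeds TCL 1.6 but cell is not marked as an exceedance while -1.66 in the same row is; inconsistent with any single threshold
UC,CL,high,2,-1.75,magnitude exceeds TCL 1.6 but cell is not marked as an exceedance while -1.76 at the other level is; inconsistent with any single threshold
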