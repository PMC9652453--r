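# SureCell [ddSEQ, Bio-Rad]
name = surecell
display_name = SureCell [ddSEQ, Bio-Rad]
barcode_total_length = 18
umi_length = 8
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,6,barcode
segment = R1,6,4,linker
segment = R1,10,6,barcode
segment = R1,16,4,linker
segment = R1,20,6,barcode
segment = R1,26,8,umi
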