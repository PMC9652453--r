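# ICELL8 (version 3) [ICELL8, Takara Bio]
name = icell8
display_name = ICELL8 (version 3) [ICELL8, Takara Bio]
barcode_total_length = 11
umi_length = 14
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,11,barcode
segment = R1,11,14,umi
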