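# BD Rhapsody [BD Rhapsody, BD]
name = bd-rhapsody
display_name = BD Rhapsody [BD Rhapsody, BD]
barcode_total_length = 27
umi_length = 8
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,27,barcode
segment = R1,27,8,umi
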