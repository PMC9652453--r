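# inDrop (version 3)
name = indrops-v3
display_name = inDrop (version 3)
barcode_total_length = 16
umi_length = 6
umi_before_barcode = false
elements_in_r2 = false
dual_index = true
linker_fill = 
whitelist_source = file
segment = R1,0,8,barcode
segment = R1,8,8,barcode
segment = R1,16,6,umi
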