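# inDrop (version 1)
name = indrops-v1
display_name = inDrop (version 1)
barcode_total_length = 19
umi_length = 6
umi_before_barcode = false
elements_in_r2 = true
dual_index = false
linker_fill = CAG
whitelist_source = file
segment = R2,0,8,barcode
segment = R2,8,4,linker
segment = R2,12,8,barcode
segment = R2,20,6,umi
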