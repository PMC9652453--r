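# 10x (version 1) [Chromium, 10x Genomics]
name = 10x-v1
display_name = 10x (version 1) [Chromium, 10x Genomics]
barcode_total_length = 14
umi_length = 10
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,14,barcode
segment = R1,14,10,umi
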