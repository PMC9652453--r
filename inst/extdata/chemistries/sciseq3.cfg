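# SCI-seq (3-level indexing)
name = sciseq3
display_name = SCI-seq (3-level indexing)
barcode_total_length = 40
umi_length = 8
umi_before_barcode = true
elements_in_r2 = false
dual_index = true
linker_fill = 
whitelist_source = file
segment = R1,0,8,umi
segment = R1,8,40,barcode
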