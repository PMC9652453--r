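# STRT-Seq-C1
name = strt-seq-c1
display_name = STRT-Seq-C1
barcode_total_length = 8
umi_length = 5
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,8,barcode
segment = R1,8,5,umi
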