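# STRT-Seq-2i
name = strt-seq-2i
display_name = STRT-Seq-2i
barcode_total_length = 13
umi_length = 6
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,13,barcode
segment = R1,13,6,umi
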