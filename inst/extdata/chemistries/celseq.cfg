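# CEL-Seq
name = celseq
display_name = CEL-Seq
barcode_total_length = 8
umi_length = 4
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,8,barcode
segment = R1,8,4,umi
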