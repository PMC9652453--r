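# CEL-Seq2
name = celseq2
display_name = CEL-Seq2
barcode_total_length = 6
umi_length = 6
umi_before_barcode = true
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,6,umi
segment = R1,6,6,barcode
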