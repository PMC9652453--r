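# MARS-Seq 2.0
name = marsseq-v2
display_name = MARS-Seq 2.0
barcode_total_length = 7
umi_length = 8
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,7,barcode
segment = R1,7,8,umi
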