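# MARS-Seq
name = marsseq-v1
display_name = MARS-Seq
barcode_total_length = 6
umi_length = 10
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,6,barcode
segment = R1,6,10,umi
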