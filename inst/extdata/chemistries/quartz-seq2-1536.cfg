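# Quartz-Seq2 (1536 wells)
name = quartz-seq2-1536
display_name = Quartz-Seq2 (1536 wells)
barcode_total_length = 15
umi_length = 8
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,15,barcode
segment = R1,15,8,umi
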