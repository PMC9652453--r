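# SPLiT-Seq [Parse Biosciences]
name = splitseq
display_name = SPLiT-Seq [Parse Biosciences]
barcode_total_length = 18
umi_length = 10
umi_before_barcode = true
elements_in_r2 = true
dual_index = false
linker_fill = 
whitelist_source = file
segment = R2,0,10,umi
segment = R2,10,6,barcode
segment = R2,16,4,linker
segment = R2,20,6,barcode
segment = R2,26,4,linker
segment = R2,30,6,barcode
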