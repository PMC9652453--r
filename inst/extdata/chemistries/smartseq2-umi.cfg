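# SMART-Seq (version 2, UMI)
name = smartseq2-umi
display_name = SMART-Seq (version 2, UMI)
barcode_total_length = 16
umi_length = 8
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,16,barcode
segment = R1,16,8,umi
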