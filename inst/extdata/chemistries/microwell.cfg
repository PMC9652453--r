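# Microwell-Seq
name = microwell
display_name = Microwell-Seq
barcode_total_length = 18
umi_length = 6
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,18,barcode
segment = R1,18,6,umi
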