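# C1 CAGE [C1, Fluidigm]
name = c1-cage
display_name = C1 CAGE [C1, Fluidigm]
barcode_total_length = 16
umi_length = none
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,16,barcode
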