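# Nadia [Nadia, Dolomite Bio]
name = nadia
display_name = Nadia [Nadia, Dolomite Bio]
barcode_total_length = 12
umi_length = 8
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,12,barcode
segment = R1,12,8,umi
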