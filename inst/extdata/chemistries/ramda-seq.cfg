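# RamDA-Seq
name = ramda-seq
display_name = RamDA-Seq
barcode_total_length = 6
umi_length = none
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = permutations
segment = R1,0,6,barcode
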