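# ICELL8 (version 3, 5') [ICELL8, Takara Bio]
name = icell8-5-prime
display_name = ICELL8 (version 3, 5') [ICELL8, Takara Bio]
barcode_total_length = 10
umi_length = none
umi_before_barcode = false
elements_in_r2 = false
dual_index = false
linker_fill = 
whitelist_source = file
segment = R1,0,10,barcode
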