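exchange_id	category	uptake_bound	secretion_bound
EX_glc	nutrient	10	NA
EX_o2	iron_oxygen	NA	NA
EX_lac	nutrient	0	NA
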