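reaction_id	directive	value
FACOAL150	make-irreversible	NA
RE1514M	make-irreversible	NA
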