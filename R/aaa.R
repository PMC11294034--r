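# Shared constants (file sorts first so every other file can use them at
# load time).

.SEXES <- c("f", "m")

.STAGES <- c("1y_nonbr", "1y_br", "2y_nonbr", "2y_br", "ad_br", "imm_br")
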