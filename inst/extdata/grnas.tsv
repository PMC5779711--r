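# Guide RNA table. cut_offset is measured in bp from the PAM-proximal end
# of the protospacer (SpCas9 default geometry: blunt cut 3 bp 5' of the
# PAM). Spacers here are demo targets; define your own guides per project.
name	spacer	pam	cut_offset
demo_SpCas9	GTTACGCATCAGGTCCTAAG	NGG	3
demo_SpCas9_b	CCATGGTTAACGGATCTTGA	NGG	3
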