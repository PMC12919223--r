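# role: exclusion
# synthetic stand-in for dementia-associated control exclusions
G31
F04
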