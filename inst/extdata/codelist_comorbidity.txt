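# role: comorbidity
# synthetic stand-in for known ADRD comorbidity prefixes
I10
E11
I25
I50
I63
F32
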