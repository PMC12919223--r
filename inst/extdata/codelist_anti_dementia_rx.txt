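# role: anti-dementia-rx
# synthetic stand-in: therapeutic stem of anti-dementia prescriptions
rxNCH
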