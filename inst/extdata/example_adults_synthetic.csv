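group,mean,sd
adult_female,10,0.5
adult_all,10,0.5
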