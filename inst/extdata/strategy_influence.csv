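,OE,RG,HP
OE,0,4,3
RG,3,0,3
HP,3,4,0
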