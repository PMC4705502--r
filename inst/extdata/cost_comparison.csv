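,AC,T,HR
AC,1,9,8
T,1/9,1,1/9
HR,1/8,9,1
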