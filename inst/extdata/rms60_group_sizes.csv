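group,n
all,60
e1,11
e2,11
a1,18
a2,10
na,10
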