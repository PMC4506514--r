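group,count
all,24
e1,6
e2,9
a1,3
a2,2
na,4
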