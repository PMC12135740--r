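type,n,readable_n
Flat,307,209
Hack,128,77
Trot,41,36
Jumping,129,103
XC_School,46,36
Gallop,324,251
Competition,27,25
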