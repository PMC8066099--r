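institution,pcr,pr1,pr2
A,66,45,45
B,8,9,10
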