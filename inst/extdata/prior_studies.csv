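label,events,n
Hinoul 2008,8,76
Abdel-Fattah 2008,5,48
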