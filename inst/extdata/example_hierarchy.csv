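child,parent
PA,
S1,PA
S1A,S1
S01.151,S1A
S01.001,S1A
CA,
C1,CA
C01.032,C1
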