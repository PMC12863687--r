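>FAM1 synthetic
A [ 3 9 12 3 3 5 4 3 ]
C [ 6 7 4 12 5 12 12 2 ]
G [ 12 4 9 4 3 5 3 6 ]
T [ 3 12 5 2 12 5 3 12 ]
>FAM2 synthetic
A [ 8 2 12 9 5 4 4 5 ]
C [ 4 6 3 12 5 12 12 8 ]
G [ 12 3 4 8 4 4 9 9 ]
T [ 5 12 2 4 12 3 4 12 ]
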