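pair	percent
A/G	27.02
C/T	25.51
A/T	13.36
A/C	12.10
G/T	11.50
C/G	10.53
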