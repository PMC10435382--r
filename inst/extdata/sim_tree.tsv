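code	parent
P1	root
P2	root
P3	root
P4	root
P5	root
P1.1	P1
P1.2	P1
P1.3	P1
P2.1	P2
P2.2	P2
P2.3	P2
P3.1	P3
P3.2	P3
P3.3	P3
P4.1	P4
P4.2	P4
P4.3	P4
P5.1	P5
P5.2	P5
P5.3	P5
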