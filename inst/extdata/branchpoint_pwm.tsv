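base	b1	b2	b3	b4	b5
A	0.12	0.08	0.3	0.96	0.1
C	0.38	0.07	0.25	0.01	0.45
G	0.1	0.05	0.2	0.01	0.1
T	0.4	0.8	0.25	0.02	0.35
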