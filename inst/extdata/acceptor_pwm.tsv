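base	m20	m19	m18	m17	m16	m15	m14	m13	m12	m11	m10	m9	m8	m7	m6	m5	m4	m3	m2	m1	p1	p2	p3
A	0.1	0.09	0.08	0.09	0.09	0.09	0.08	0.07	0.08	0.08	0.09	0.09	0.09	0.09	0.08	0.07	0.24	0.06	0.97	0.01	0.25	0.3	0.25
C	0.28	0.3	0.3	0.29	0.31	0.3	0.31	0.32	0.33	0.34	0.35	0.36	0.37	0.38	0.39	0.36	0.28	0.4	0.01	0.01	0.15	0.25	0.22
G	0.12	0.11	0.11	0.12	0.1	0.1	0.11	0.1	0.1	0.09	0.09	0.08	0.09	0.08	0.08	0.07	0.22	0.04	0.01	0.97	0.5	0.2	0.28
T	0.5	0.5	0.51	0.5	0.5	0.51	0.5	0.51	0.49	0.49	0.47	0.47	0.45	0.45	0.45	0.5	0.26	0.5	0.01	0.01	0.1	0.25	0.25
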