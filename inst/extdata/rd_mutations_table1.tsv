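gene	hgvs_c	protein	status	reference
ABCA4	c.287delA	p.N96Tfs*19	novel	
ABCA4	c.6148G>C	p.V2050L	known	Allikmets et al.
ABCA4	c.4720G>T	p.E1574*	known	Maia-Lopes et al.
ABCA4	c.950delG	p.G317Afs*57	novel	
ABCA4	c.2285C>A	p.A762E	known	Aguirre-Lamban et al.
CHM	c.863dupA	p.M289Y*18	novel	
USH2A	c.920_923dupGCCA	p.H308Qfs*16	known	Weston et al.
USH2A	c.12574C>T	p.R4192C	novel	
CNGB3	c.1148delC	p.T383Ifs*13	known	Sundin et al.
CNGB3	c.1666G>T	p.E556*	novel	
RP1	c.1625C>G	p.S542*	novel	
RP1	c.4804C>T	p.Q1602*	novel	
RP1	c.5173C>T	p.Q1725*	novel	
NMNAT1	c.507G>A	p.W169*	known	Chiang et al.
NMNAT1	c.769G>A	p.E257K	known	Chiang et al.
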