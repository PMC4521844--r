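# Synthetic position-weight profile for one 34-residue TPR repeat.
# Weights are additive log-odds-style scores; only the canonical small/large
# hydrophobic signature positions of the TPR consensus carry weight
# (positions 4, 7, 8, 11, 20, 24, 27, 32). A window's score is the sum over
# positions of the weight of the residue observed there. Subordinate to
# external domain annotations; used only so the synthetic pipeline can run
# without external domain-scanning tools.
position	residues	weight
4	W	2.0
4	FY	1.0
7	L	2.0
7	IVM	1.0
8	G	2.0
8	A	1.0
11	Y	2.0
11	FW	1.0
20	A	2.0
20	GS	1.0
24	F	2.0
24	YL	1.0
27	A	2.0
27	SG	1.0
32	P	2.0
32	A	1.0
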