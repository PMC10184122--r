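# Published per-complex totals (kcal/mol) of the three per-bond rupture
# free energies; wt_noLEN, N39G and G40N disagree with the sum of their
# printed components at one decimal and are flagged, not corrected.
complex	total	error
wt_LEN	28.0	0.7
wt_noLEN	12.4	1.1
I35G	24.5	0.7
I37E	22.7	0.8
N39G	16.9	1.1
G40N	12.4	2.4
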