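# Measured K+, Na+, Cl- and water contents of U937 cells during
# staurosporine-induced apoptosis (means; contents umol per g protein,
# water ml per g protein). Impermeant-anion content A- inferred from
# electroneutrality.
time	k	na	cl	a_anion	water
0	712	192	246	658	6.08
30	615	175	133	657	5.37
120	595	179	109	665	4.70
240	493	261	117	637	4.85
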