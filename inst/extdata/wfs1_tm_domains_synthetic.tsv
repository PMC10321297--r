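# protein_id: SYNP01
# provenance: SYNTHETIC transmembrane ranges bundled with wfsdose for tests and simulation; not retrieved from any annotation database and not suitable for analysing real WFS1 variants
# coordinates: 1-based residue positions, closed intervals
start	end	label
311	331	TM1
342	362	TM2
383	403	TM3
418	438	TM4
446	466	TM5
494	514	TM6
529	549	TM7
561	581	TM8
627	647	TM9
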