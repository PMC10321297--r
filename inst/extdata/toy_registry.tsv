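patient_id	sex	allele1	allele2	onset_dm	onset_oa	onset_di	onset_hl	source
P001	female	p.Arg558Cys	p.Trp613*	6.0	11.0	13.0	14.0	registry
P002	male	p.Val412Serfs*29	p.Val412Serfs*29	4.5	10.0			registry
P003	male	p.Phe883del	p.Arg321Trp	8.0		15.5	16.0	literature
P004	female		p.Arg558Cys	7.0	12.0			registry
P005	male	p.Trp613*		5.0	9.0	12.0		literature
P006	female	p.Arg558Cys	p.Phe883del		13.0		18.0	registry
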