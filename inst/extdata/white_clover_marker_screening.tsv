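source	n_screened	n_polymorphic	n_mapped_markers	n_mapped_loci
WCS	1973	874	814	1200
RCS	2518	305	282	412
prs	32	18	17	20
ats	30	27	27	41
TRSSR	26	22	20	26
MTIC	2	2	2	3
other_Mt_EST	36	28	25	38
MT1	2	2	2	3
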