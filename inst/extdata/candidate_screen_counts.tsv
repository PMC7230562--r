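# Carrier counts of the 13 validated candidate variants from the hereditary-melanoma
# screening cohort: 26 multiple-primary-melanoma cases (8 whole-exome + 18 screened),
# 37 familial-melanoma indexes, and 100-300 healthy controls (denominators vary per
# variant). control_hom marks variants observed homozygous in a healthy control.
# aggregation_set marks the variant panel entering the region-based aggregation tests.
# Genomic positions are synthetic placeholders (coordinates are not used downstream).
gene	chrom	pos	hgvs_c	hgvs_p	consequence	mpm_carriers	mpm_n	index_carriers	index_n	control_carriers	control_n	control_hom	aggregation_set
NTN4	12	1000	c.1182C>T	p.Pro394=	exonic_synonymous	4	26	0	37	5	200	0	1
MTCL1	18	2000	c.4315G>A	p.Gly1439Ser	exonic_missense	5	26	2	37	4	100	0	1
MAP2K3	17	3000	c.77G>C	p.Arg26Thr	exonic_missense	22	26	33	37	92	100	0	0
CAND2	3	4000	c.992A>T	p.Glu331Val	exonic_missense	3	26	1	37	3	100	0	1
RPL32	3	5000	c.98G>A	p.Arg33His	exonic_missense	3	26	1	37	2	100	0	1
FNDC1	6	6000	c.3332G>A	p.Asp1112Asn	exonic_missense	3	26	1	37	5	100	0	1
CDH23	10	7000	c.1096G>A	p.Ala366Thr	exonic_missense	2	26	0	37	2	300	0	0
CFAP47	X	8000	c.4589A>C	p.His1530Pro	exonic_missense	3	26	2	37	3	100	1	0
BMX	X	9000	c.851C>T	p.Ser284Leu	exonic_missense	3	26	1	37	1	100	1	0
ITIH3	3	10000	c.1130G>A	p.Arg377Gln	exonic_missense	4	26	0	37	2	100	0	1
RNF213	17	11000	c.2122C>G	p.His708Asp	exonic_missense	4	26	2	37	3	100	0	1
ARHGEF40	14	12000	c.2500C>T	p.Arg834Cys	exonic_missense	3	26	0	37	0	100	0	0
BRD9	5	13000	c.183G>C	p.Glu61Asp	exonic_missense	4	26	0	37	0	100	0	0
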