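chr1	0	30000	rightward_domain_1	0	+
chr1	30000	60000	leftward_domain_1	0	-
chr1	60000	90000	rightward_domain_2	0	+
chr1	90000	120000	leftward_domain_2	0	-
chr2	0	25000	rightward_domain_3	0	+
chr2	25000	50000	leftward_domain_3	0	-
chr2	50000	75000	rightward_domain_4	0	+
chr2	75000	100000	leftward_domain_4	0	-
chr3	0	20000	rightward_domain_5	0	+
chr3	20000	40000	leftward_domain_5	0	-
chr3	40000	60000	rightward_domain_6	0	+
chr3	60000	80000	leftward_domain_6	0	-
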