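haplotype_id	Española	Fernandina	Floreana	Genovesa	Isabela	San Cristóbal	Santa Cruz	Santa Fe	Santiago
h3	0	8	3	3	30	0	4	0	5
h4	0	6	0	0	17	0	0	2	0
h5	0	0	0	0	4	0	0	0	0
h6	0	0	0	0	3	0	0	0	0
h7	0	0	0	0	2	0	0	0	0
h8	0	0	0	0	2	0	0	0	0
h9	0	0	0	0	0	0	3	0	0
h10	0	0	3	0	0	0	0	0	0
h11	4	0	0	0	0	6	0	0	0
h12	0	0	0	0	0	5	0	0	0
h13	0	0	0	0	0	4	0	0	0
h14	0	0	0	0	0	4	0	0	0
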