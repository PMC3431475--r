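# Published per-chromosome distribution of candidate allergen proteins
# (celiac disease and wheat allergy classes) and of proteins still carrying
# an intact epitope after simultaneous trypsin/pepsin/chymotrypsin digestion,
# plus the overall count of distinct seed-expressed candidates (the two
# disease classes overlap, so the union is smaller than their sum).
disease	chromosome	n_proteins	n_resistant
CD	1	56	49
CD	2	35	21
CD	3	39	33
CD	4	26	24
CD	5	11	11
WA	1	11	5
WA	2	20	12
WA	3	7	6
WA	4	5	4
WA	5	4	3
union	all	206	NA
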