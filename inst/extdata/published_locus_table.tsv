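pattern	candidate_loci	corrected_loci	ervs_adjacent_genes	genes_adjacent_ervs
H--	874	38	11	29
-L-	1109	52	19	38
--W	616	117	46	95
HL-	2966	103	19	36
H-W	1227	30	9	11
-LW	1548	29	11	20
HLW	4369	NA	NA	NA
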