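pair	n_regions	background_selection	adaptation_river	adaptation_lake	reduced_gene_flow
Us	152	18	20	43	52
G2	149	21	51	24	45
No	173	24	69	35	43
G1	192	21	51	43	64
Ca	128	10	23	20	70
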