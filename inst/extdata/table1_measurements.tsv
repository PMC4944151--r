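id	residue	j12	j23	j34	j45	noe_ratio	nsulfo	sulfo6	sulfo3
1	IdoA2S	2.2	4.3	3.2	2.2	0.19	FALSE	FALSE	FALSE
2	IdoA2S	2.2	4.3	3.2	2.3	0.21	TRUE	FALSE	FALSE
3	IdoA2S	3	5.8	3.6	2.7	0.26	TRUE	TRUE	FALSE
4	IdoA2S	3.7	7.4	4	3.1	0.34	TRUE	TRUE	TRUE
5	IdoA	3	5.2	3.5	2.7	0.34	FALSE	FALSE	FALSE
6	IdoA	3.1	5.3	3.5	2.7	0.35	TRUE	FALSE	FALSE
7	IdoA	2.3	4.3	3.4	2.4	0.22	TRUE	TRUE	FALSE
8	IdoA	2.3	3.9	3.5	2.2	0.19	TRUE	TRUE	TRUE
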