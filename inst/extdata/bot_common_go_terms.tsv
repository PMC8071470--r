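order	term	name	rank_all_bot	rank_sbot	rank_mbot	category
1	GO:0002682	Regulation of immune system process	1	1	2	immune_inflammatory
2	GO:0044281	Small molecule metabolic process	5	5	1	metabolism
3	GO:0001775	Cell activation	2	3	7	cycle_signaling
4	GO:0006811	Ion transport	4	4	4	membrane_transporter
5	GO:0005215	Transporter activity	3	2	9	membrane_transporter
6	GO:0051049	Regulation of transport	6	6	3	membrane_transporter
7	GO:0045595	Regulation of cell differentiation	10	10	5	cycle_signaling
8	GO:0001816	Cytokine production	9	9	10	cycle_signaling
9	GO:0002520	Immune system development	8	8	13	immune_inflammatory
10	GO:0006629	Lipid metabolic process	11	12	6	metabolism
11	GO:0002252	Immune effector process	7	7	21	immune_inflammatory
12	GO:0042592	Homeostatic process	14	14	15	cycle_signaling
13	GO:0031399	Regulation of protein modification process	13	11	24	metabolism
14	GO:0040011	Locomotion	12	27	12	membrane_transporter
15	GO:0051240	Positive regulation of multicellular organismal process	17	17	17	cycle_signaling
16	GO:0046903	Secretion	15	19	19	membrane_transporter
17	GO:0007267	Cell-cell signaling	16	23	14	cycle_signaling
18	GO:0016070	RNA metabolic process	20	26	8	metabolism
19	GO:0048585	Negative regulation of response to stimulus	18	13	28	cycle_signaling
20	GO:0051276	Chromosome organization	22	22	16	cycle_signaling
21	GO:0060429	Epithelium development	24	20	20	others
22	GO:0006915	Apoptotic process	21	18	26	cycle_signaling
23	GO:0007049	Cell cycle	25	24	27	cycle_signaling
24	GO:0033043	Regulation of organelle organization	27	28	22	cycle_signaling
25	GO:0022610	Biological adhesion	19	15	45	membrane_transporter
26	GO:0051174	Regulation of phosphorus metabolic process	26	21	32	metabolism
27	GO:0019219	Regulation of nucleobase-containing compound metabolic process	30	31	18	metabolism
28	GO:0055085	Transmembrane transport	23	16	41	membrane_transporter
29	GO:0022008	Neurogenesis	32	38	11	others
30	GO:0070727	Cellular macromolecule localization	28	25	31	membrane_transporter
31	GO:0006259	DNA metabolic process	35	34	23	metabolism
32	GO:0023056	Positive regulation of signaling	31	30	35	cycle_signaling
33	GO:0046907	Intracellular transport	29	29	39	membrane_transporter
34	GO:0051241	Negative regulation of multicellular organismal process	36	33	38	cycle_signaling
35	GO:0005102	Signaling receptor binding	33	35	43	cycle_signaling
36	GO:0006468	Protein phosphorylation	34	32	47	metabolism
37	GO:0000003	Reproduction	43	49	25	others
38	GO:0080134	Regulation of response to stress	40	37	42	cycle_signaling
39	GO:0009719	Response to endogenous stimulus	41	50	29	cycle_signaling
40	GO:0044419	Interspecies interaction between organisms	37	40	46	others
41	GO:0018193	Peptidyl-amino acid modification	44	47	40	metabolism
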