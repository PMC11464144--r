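GENE	CYTOBAND	SUBSET	PRIMARY	P_CR	P_CYS	P_SRAGE	P_CMA
MTX1	1q22	cr_cys_sRAGE	1	2.66e-5	1.63e-3	2.61e-4	1.99e-7
MTX1	1q22	cr_sRAGE	0	2.66e-5		2.61e-4	1.1e-7
PTPRC	1q31.3-q32.1	cr_cys_sRAGE	1	1.7e-5	2.87e-5	3.58e-2	6.63e-7
PTPRC	1q31.3-q32.1	cr_cys	0	1.7e-5	2.87e-5		1.45e-6
ODC1	2p25.1	cr_cys	1	1.47e-6	3.54e-6		7.62e-8
CALM2	2p21	cr_cys	1	3.37e-5	7.9e-6		9.93e-7
TEC	4p12-p11	cr_cys_sRAGE	1	2.08e-4	3.21e-5	1.37e-2	1.17e-6
CCNI	4q21.1	cr_cys_sRAGE	1	3.35e-4	1.19e-4	6.18e-3	1.69e-6
ERGIC1	5q35.1	cr_cys	1	3.31e-5	2.34e-7		1.17e-7
DAAM2	6p21.2	cr_cys_sRAGE	1	3.69e-6	4.59e-6	2.85e-3	7.28e-9
DAAM2	6p21.2	cr_cys	0	3.69e-6	4.59e-6		1.63e-7
DAAM2	6p21.2	cr_sRAGE	0	3.69e-6		2.85e-3	2.86e-7
DAAM2	6p21.2	cys_sRAGE	0		4.59e-6	2.85e-3	3.40e-7
DAAM2-AS1	6p21.2	cr_cys_sRAGE	1	2.47e-4	1.46e-4	6.41e-3	1.63e-6
SNTB1	8q24.12	cr_cys	1	2.48e-5	1.45e-5		1.19e-6
TOPORS	9p21.1	cr_cys	1	5.92e-5	5.21e-6		1.13e-6
LSP1	11p15.5	cr_cys	1	1.93e-4	8.41e-7		8.97e-7
ATG2A	11q13.1	cr_cys	1	8.74e-6	2.05e-5		7.6e-7
RPL18P10	13q14.2	cr_cys	1	1.19e-4	7.65e-6		2.31e-6
C16orf54	16p11.2	cr_cys_sRAGE	1	1.92e-6	3.94e-7	1.39e-2	5.89e-9
C16orf54	16p11.2	cr_cys	0	1.92e-6	3.94e-7		2.2e-8
C16orf54	16p11.2	cr_sRAGE	0	1.92e-6		1.39e-2	1.27e-6
MIR23AHG	19p13.12	cr_cys_sRAGE	1	3.59e-5	1.76e-3	3.05e-3	1.49e-6
MIR23AHG	19p13.12	cr_sRAGE	0	3.59e-5		3.05e-3	1.81e-6
TP53INP2	20q11.22	cr_cys_sRAGE	1	2.16e-4	3.73e-6	6.48e-2	1.96e-6
TP53INP2	20q11.22	cr_cys	0	2.16e-4	3.73e-6		2.31e-6
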