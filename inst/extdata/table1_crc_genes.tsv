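gene	nN	nT	pctN	pctT	product
POU5F1B	11	186	3.8	65.0	canon.
HTR1D	9	175	3.1	61.2	canon.
SLCO1B3	6	159	2.1	55.6	N-trunc.
CMTR1	2	149	0.7	52.1	C-trunc.
ABLIM2	1	111	0.3	38.8	N-ext.
NCALD	28	124	9.8	43.4	canon.
SLC22A3	25	119	8.7	41.6	N-trunc.; N-C-trunc.
PMPCB	7	94	2.4	32.9	N-C-trunc.; out.frame; C-trunc.
CAPN12	2	75	0.7	26.2	canon.; C-trunc.
FGGY	8	80	2.8	28.0	canon.; N-trunc.
TRAF2	8	80	2.8	28.0	canon.; N-ext.
ATP5J2	13	85	4.5	29.7	canon.
RNF43	3	71	1.0	24.8	canon.; N-ext.
EDAR	0	66	0.0	23.1	N-ext.
TM9SF2	4	70	1.4	24.5	canon.
CEP72	25	91	8.7	31.8	N-trunc.; N-C-trunc.
TSSC1	9	73	3.1	25.5	N-trunc.; C-ext.
KRT8	7	67	2.4	23.4	N-ext.
WFDC3	24	83	8.4	29.0	N-trunc.
PALD1	16	74	5.6	25.9	canon.; C-trunc.; out.frame
SBF2	12	69	4.2	24.1	out.frame; N-trunc.
SPACA3	3	58	1.0	20.3	N-ext.
MCCC2	6	61	2.1	21.3	out.frame; N-C-trunc.
POMZP3	20	70	7.0	24.5	canon.; C-trunc.
TNRC18	22	72	7.7	25.2	N-trunc.; N-C-trunc.
BMP7	12	62	4.2	21.7	out.frame
ABHD2	13	63	4.5	22.0	canon.
TGIF2	14	63	4.9	22.0	canon.
ST3GAL2	23	70	8.0	24.5	canon.
ZNF283	19	66	6.6	23.1	canon.; out.frame
ADAP1	16	63	5.6	22.0	canon.
CLSTN3	23	66	8.0	23.1	canon.
CLDN4	16	58	5.6	20.3	canon.
FAM110A	17	59	5.9	20.6	canon.
DAP3	27	67	9.4	23.4	N-trunc.; out.frame
PTPDC1	27	67	9.4	23.4	canon.; N-trunc.
PMFBP1	20	58	7.0	20.3	canon.; C-trunc.; N-C-trunc.
TXLNG	26	63	9.1	22.0	N-C-trunc.
ZNF710	26	60	9.1	21.0	N-ext.
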