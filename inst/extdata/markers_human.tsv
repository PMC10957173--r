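gene	cell_type	rank
SNAP25	neuron	1
RBFOX3	neuron	2
SYT1	neuron	3
STMN2	neuron	4
SYN1	neuron	5
GABRA1	neuron	6
NEFL	neuron	7
GRIN1	neuron	8
SLC17A7	neuron	9
GAD1	neuron	10
NRGN	neuron	11
CAMK2A	neuron	12
DLG4	neuron	13
MAP2	neuron	14
TUBB3	neuron	15
AQP4	astrocyte	1
GJA1	astrocyte	2
GFAP	astrocyte	3
SLC1A2	astrocyte	4
SLC1A3	astrocyte	5
ALDH1L1	astrocyte	6
S100B	astrocyte	7
SOX9	astrocyte	8
GJB6	astrocyte	9
FGFR3	astrocyte	10
NDRG2	astrocyte	11
MLC1	astrocyte	12
SLC4A4	astrocyte	13
GPR37L1	astrocyte	14
BMPR1B	astrocyte	15
MBP	oligodendrocyte	1
MOG	oligodendrocyte	2
MOBP	oligodendrocyte	3
PLP1	oligodendrocyte	4
MAG	oligodendrocyte	5
CNP	oligodendrocyte	6
CLDN11	oligodendrocyte	7
SOX10	oligodendrocyte	8
OPALIN	oligodendrocyte	9
MAL	oligodendrocyte	10
UGT8	oligodendrocyte	11
ASPA	oligodendrocyte	12
ERMN	oligodendrocyte	13
GJB1	oligodendrocyte	14
TF	oligodendrocyte	15
AIF1	microglia	1
CX3CR1	microglia	2
P2RY12	microglia	3
TMEM119	microglia	4
CSF1R	microglia	5
C1QA	microglia	6
C1QB	microglia	7
C1QC	microglia	8
ITGAM	microglia	9
TYROBP	microglia	10
TREM2	microglia	11
CD74	microglia	12
PTPRC	microglia	13
LAPTM5	microglia	14
CTSS	microglia	15
CLDN5	endothelial	1
FLT1	endothelial	2
PECAM1	endothelial	3
VWF	endothelial	4
CDH5	endothelial	5
TEK	endothelial	6
ESAM	endothelial	7
SLC2A1	endothelial	8
ABCB1	endothelial	9
OCLN	endothelial	10
ITM2A	endothelial	11
TIE1	endothelial	12
ENG	endothelial	13
CD34	endothelial	14
A2M	endothelial	15
PDGFRA	OPC	1
CSPG4	OPC	2
OLIG1	OPC	3
OLIG2	OPC	4
GPR17	OPC	5
LHFPL3	OPC	6
MEGF11	OPC	7
PCDH15	OPC	8
VCAN	OPC	9
NEU4	OPC	10
SUSD5	OPC	11
BCAN	OPC	12
SOX6	OPC	13
EPN2	OPC	14
CA10	OPC	15
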