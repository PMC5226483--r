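label	name	x	y	z
PreCG.L	Precentral gyrus	-39	-6	51
PreCG.R	Precentral gyrus	41	-8	52
SFGdor.L	Superior frontal gyrus, dorsolateral	-18	35	42
SFGdor.R	Superior frontal gyrus, dorsolateral	22	31	44
ORBsup.L	Superior frontal gyrus, orbital part	-17	47	-13
ORBsup.R	Superior frontal gyrus, orbital part	18	48	-14
MFG.L	Middle frontal gyrus	-33	33	35
MFG.R	Middle frontal gyrus	38	33	34
ORBmid.L	Middle frontal gyrus, orbital part	-31	50	-10
ORBmid.R	Middle frontal gyrus, orbital part	33	53	-11
IFGoperc.L	Inferior frontal gyrus, opercular part	-48	13	19
IFGoperc.R	Inferior frontal gyrus, opercular part	50	15	21
IFGtriang.L	Inferior frontal gyrus, triangular part	-46	30	14
IFGtriang.R	Inferior frontal gyrus, triangular part	50	30	14
ORBinf.L	Inferior frontal gyrus, orbital part	-36	31	-12
ORBinf.R	Inferior frontal gyrus, orbital part	41	32	-12
ROL.L	Rolandic operculum	-47	-8	14
ROL.R	Rolandic operculum	53	-6	15
SMA.L	Supplementary motor area	-5	5	61
SMA.R	Supplementary motor area	9	0	62
OLF.L	Olfactory cortex	-8	15	-11
OLF.R	Olfactory cortex	10	16	-11
SFGmed.L	Superior frontal gyrus, medial	-5	49	31
SFGmed.R	Superior frontal gyrus, medial	9	51	30
ORBsupmed.L	Superior frontal gyrus, medial orbital	-5	54	-7
ORBsupmed.R	Superior frontal gyrus, medial orbital	8	52	-7
REC.L	Gyrus rectus	-5	37	-18
REC.R	Gyrus rectus	8	36	-18
INS.L	Insula	-35	7	3
INS.R	Insula	39	6	2
ACG.L	Anterior cingulate and paracingulate gyri	-4	35	14
ACG.R	Anterior cingulate and paracingulate gyri	8	37	16
DCG.L	Median cingulate and paracingulate gyri	-5	-15	42
DCG.R	Median cingulate and paracingulate gyri	8	-9	40
PCG.L	Posterior cingulate gyrus	-5	-43	25
PCG.R	Posterior cingulate gyrus	7	-42	22
HIP.L	Hippocampus	-25	-21	-10
HIP.R	Hippocampus	29	-20	-10
PHG.L	Parahippocampal gyrus	-21	-16	-21
PHG.R	Parahippocampal gyrus	25	-15	-20
AMYG.L	Amygdala	-23	-1	-17
AMYG.R	Amygdala	27	1	-18
CAL.L	Calcarine fissure and surrounding cortex	-7	-79	6
CAL.R	Calcarine fissure and surrounding cortex	16	-73	9
CUN.L	Cuneus	-6	-80	27
CUN.R	Cuneus	14	-79	28
LING.L	Lingual gyrus	-15	-68	-5
LING.R	Lingual gyrus	16	-67	-4
SOG.L	Superior occipital gyrus	-17	-84	28
SOG.R	Superior occipital gyrus	24	-81	31
MOG.L	Middle occipital gyrus	-32	-81	16
MOG.R	Middle occipital gyrus	37	-80	19
IOG.L	Inferior occipital gyrus	-36	-78	-8
IOG.R	Inferior occipital gyrus	38	-82	-8
FFG.L	Fusiform gyrus	-31	-40	-20
FFG.R	Fusiform gyrus	34	-39	-20
PoCG.L	Postcentral gyrus	-42	-23	49
PoCG.R	Postcentral gyrus	41	-25	53
SPG.L	Superior parietal gyrus	-23	-60	59
SPG.R	Superior parietal gyrus	26	-59	62
IPL.L	Inferior parietal, supramarginal and angular gyri	-43	-46	47
IPL.R	Inferior parietal, supramarginal and angular gyri	46	-46	50
SMG.L	Supramarginal gyrus	-56	-34	30
SMG.R	Supramarginal gyrus	58	-32	34
ANG.L	Angular gyrus	-44	-61	36
ANG.R	Angular gyrus	46	-60	39
PCUN.L	Precuneus	-7	-56	48
PCUN.R	Precuneus	10	-56	44
PCL.L	Paracentral lobule	-8	-25	70
PCL.R	Paracentral lobule	7	-32	68
CAU.L	Caudate nucleus	-11	11	9
CAU.R	Caudate nucleus	15	12	9
PUT.L	Lenticular nucleus, putamen	-24	4	2
PUT.R	Lenticular nucleus, putamen	28	5	2
PAL.L	Lenticular nucleus, pallidum	-18	0	0
PAL.R	Lenticular nucleus, pallidum	21	0	0
THA.L	Thalamus	-11	-18	8
THA.R	Thalamus	13	-18	8
HES.L	Heschl gyrus	-42	-19	10
HES.R	Heschl gyrus	46	-17	10
STG.L	Superior temporal gyrus	-53	-21	7
STG.R	Superior temporal gyrus	58	-22	7
TPOsup.L	Temporal pole: superior temporal gyrus	-40	15	-20
TPOsup.R	Temporal pole: superior temporal gyrus	48	15	-17
MTG.L	Middle temporal gyrus	-56	-34	-2
MTG.R	Middle temporal gyrus	57	-37	-1
TPOmid.L	Temporal pole: middle temporal gyrus	-36	15	-34
TPOmid.R	Temporal pole: middle temporal gyrus	44	15	-32
ITG.L	Inferior temporal gyrus	-50	-28	-23
ITG.R	Inferior temporal gyrus	54	-31	-22
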