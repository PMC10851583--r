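gene	group2	n_any_hlap	n_any_bap	n_path_hlap	n_path_bap
APOA5	FALSE	97	13	52	1
PLA2G6	TRUE	44	7	9	0
LIPC	TRUE	163	30	8	0
LRP1	TRUE	163	30	13	1
LMF2	TRUE	163	30	6	0
FGR	TRUE	7	1	5	0
CETP	TRUE	111	25	15	2
PLTP	TRUE	21	2	4	0
PINX1	TRUE	12	4	4	0
FRMD5	TRUE	104	14	3	0
GCKR	TRUE	84	16	3	0
IRS1	TRUE	102	17	2	0
HAVCR1	TRUE	144	29	2	0
SORL1	TRUE	163	30	7	1
PPARG	TRUE	83	8	1	0
APOBEC1	TRUE	141	25	1	0
PPARD	TRUE	151	27	1	0
TRIB1	TRUE	86	15	1	0
FADS2	TRUE	1	0	1	0
FADS3	TRUE	2	0	1	0
ANGPTL4	TRUE	36	7	1	0
MLXIPL	TRUE	162	30	1	0
GALNT2	TRUE	153	29	1	0
PPARA	TRUE	17	4	1	0
GPIHBP1	TRUE	144	29	1	0
TIMD4	TRUE	134	30	1	0
USF1	FALSE	1	0	0	0
APOC2	FALSE	0	0	0	0
MSL2L1	FALSE	0	0	0	0
MTP	FALSE	0	0	0	0
ZNF664	FALSE	3	1	0	0
FADS1	FALSE	2	1	0	0
CYP26A1	FALSE	1	1	0	0
CILP2	FALSE	18	5	0	0
APOC3	FALSE	83	23	0	0
CAPN3	FALSE	43	6	5	1
NCAN	FALSE	92	16	1	1
ANGPTL3	FALSE	9	1	1	1
XKR6	FALSE	5	1	1	1
LDLR	FALSE	155	29	1	1
LDLRAP1	FALSE	110	20	0	1
CTF1	FALSE	2	2	0	1
LPL	FALSE	22	6	16	4
TYW1B	FALSE	122	25	56	12
KLHL8	FALSE	3	2	1	2
PEPD	FALSE	133	24	28	7
APOE	FALSE	90	20	22	6
MAP3K1	FALSE	153	25	5	3
NAT2	FALSE	134	30	9	4
LMF1	FALSE	141	25	10	5
COBLL1	FALSE	52	15	17	7
JMJD1C	FALSE	151	30	21	9
APOB	FALSE	144	30	111	30
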