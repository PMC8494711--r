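#version: demo-2026.1
#updated: 2026-01-15
# Illustrative kidney-disease gene panel for demonstrations and simulation.
# SYNTHETIC, NON-CLINICAL curation: gene/category/mode assignments are
# plausible but not validated for diagnostic use.
symbol	chromosome	modes	categories	digenic_partners	lof_mechanism
PAX2	10	AD	CAKUT,GLOMERULAR		TRUE
EYA1	8	AD	CAKUT		TRUE
FRAS1	4	AR	CAKUT		TRUE
ANOS1	X	XL	CAKUT		TRUE
HNF1B	17	AD	CAKUT,TUBULAR		TRUE
SLC12A3	16	AR	TUBULAR		TRUE
SLC12A1	15	AR	TUBULAR		TRUE
CLCN5	X	XL	TUBULAR,NEPHROLITHIASIS_NEPHROCALCINOSIS		TRUE
OCRL	X	XL	TUBULAR		TRUE
CASR	3	AD	TUBULAR,NEPHROLITHIASIS_NEPHROCALCINOSIS		TRUE
AVPR2	X	XL	TUBULAR		TRUE
BSND	1	AR	TUBULAR		TRUE
PKD1	16	AD	CILIOPATHY		TRUE
PKD2	4	AD	CILIOPATHY		TRUE
PKHD1	6	AR	CILIOPATHY		TRUE
NPHP1	2	AR	CILIOPATHY	NPHP4	TRUE
NPHP4	1	AR	CILIOPATHY	NPHP1	TRUE
CEP290	12	AR	CILIOPATHY		TRUE
TMEM67	8	AR	CILIOPATHY		TRUE
OFD1	X	XL	CILIOPATHY		TRUE
AGXT	2	AR	NEPHROLITHIASIS_NEPHROCALCINOSIS		TRUE
SLC3A1	2	AR	NEPHROLITHIASIS_NEPHROCALCINOSIS		TRUE
CYP24A1	20	AD	NEPHROLITHIASIS_NEPHROCALCINOSIS		TRUE
SLC34A1	5	AD_AR	NEPHROLITHIASIS_NEPHROCALCINOSIS,TUBULAR		TRUE
COL4A3	2	AD_AR	GLOMERULAR	COL4A4	TRUE
COL4A4	2	AD_AR	GLOMERULAR	COL4A3	TRUE
COL4A5	X	XL	GLOMERULAR		TRUE
NPHS1	19	AR	GLOMERULAR	NPHS2	TRUE
NPHS2	1	AR	GLOMERULAR	NPHS1	TRUE
WT1	11	AD	GLOMERULAR		TRUE
INF2	14	AD	GLOMERULAR		TRUE
UMOD	16	AD	GLOMERULAR,TUBULAR		TRUE
CFH	1	AD	HUS		TRUE
CD46	1	AD_AR	HUS		TRUE
DGKE	17	AR	HUS		TRUE
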