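term	n_results	label	validating_ids
laevis cement gland	4	D	10095068;9790916
Xenopus laevis cement gland	4	D	10095068;9790916
AGR2 promotes cell	7	D	20048076;18199544
AGR2	70	D	20945500
XAG-2	9	D	15834940;14967811;10095068;9790916;9533957
AGR2 expression	15	D	20048076;18681322;18199544;17457305;17455144;16551856
Xenopus laevis cement	5	D	10095068;9790916
gene XAG-2	3	D	9790916;9533957
hAG-2	6	D	12592373;9790916
cement gland gene XAG-2	4	D	10095068;9790916;9533957
gland gene XAG-2	5	D	15834940;10095068;9790916;9533957
PIN lesions	127	D	20945500
laevis cement gland gene	70	D	15867376
levels of AGR2	17	D	20945500;20048076;18973922;17694278;17457305
laevis cement	118	D	15867376
lower levels of AGR2	3	S	21144054
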