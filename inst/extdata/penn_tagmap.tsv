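NN	NOUN
NNS	NOUN
NNP	NOUN
NNPS	NOUN
JJ	ADJ
JJR	ADJ
JJS	ADJ
VB	OTHER
VBD	OTHER
VBG	OTHER
VBN	OTHER
VBP	OTHER
VBZ	OTHER
DT	OTHER
IN	OTHER
CC	OTHER
TO	OTHER
PRP	OTHER
PRP$	OTHER
RB	OTHER
RBR	OTHER
RBS	OTHER
MD	OTHER
CD	OTHER
EX	OTHER
FW	OTHER
LS	OTHER
PDT	OTHER
POS	OTHER
RP	OTHER
SYM	OTHER
UH	OTHER
WDT	OTHER
WP	OTHER
WP$	OTHER
WRB	OTHER
.	OTHER
,	OTHER
:	OTHER
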