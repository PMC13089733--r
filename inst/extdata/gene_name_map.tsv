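from	to
coi	cox1
coii	cox2
coiii	cox3
co1	cox1
co2	cox2
co3	cox3
cytb	cob
cob	cob
nd1	nad1
nd2	nad2
nd3	nad3
nd4	nad4
nd4l	nad4l
nd5	nad5
nd6	nad6
12s	rrnS
16s	rrnL
s-rrna	rrnS
l-rrna	rrnL
rrns	rrnS
rrnl	rrnL
trnl(tag)	trnL1
trnl(uag)	trnL1
trnl(taa)	trnL2
trnl(uaa)	trnL2
trnl1(tag)	trnL1
trnl2(taa)	trnL2
trns(tct)	trnS1
trns(gct)	trnS1
trns(ucu)	trnS1
trns(gcu)	trnS1
trns(tga)	trnS2
trns(uga)	trnS2
trns1(gct)	trnS1
trns2(tga)	trnS2
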