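protein_a	protein_b	evidence	tissues	sources
PD-1	PTPN11	experimental	lung;liver	S01
PD-1	GRB2	experimental	lung	S02
PD-1	LCK	experimental	lung	S03
PD-1	ZAP70	predicted	lung	S04
PD-1	PD-L1	experimental	lung;breast	S05
PD-L1	CD80	experimental	lung	S06
PD-L1	CAV1	experimental	liver	S07
PD-L1	GRB2	predicted	lung	S08
TIM-3	LGALS9	experimental	lung;colon	S09
TIM-3	CEACAM1	experimental	lung	S10
TIM-3	GRB2	experimental	lung	S11
TIM-3	FYN	experimental	brain	S12
TIM-3	LCK	experimental	lung	S13
LAG-3	HLA-DRB1	experimental	lung	S14
LAG-3	FGL1	experimental	liver	S15
LAG-3	LCK	predicted	lung	S16
LAG-3	CSK	experimental	lung	S17
BTLA	TNFRSF14	experimental	lung	S18
BTLA	PTPN6	experimental	lung	S19
BTLA	PTPN11	experimental	lung	S20
BTLA	LCK	experimental	brain	S21
TIGIT	PVR	experimental	lung	S22
TIGIT	PVRL2	experimental	lung	S23
TIGIT	PTPN11	predicted	lung	S24
TIGIT	GRB2	experimental	lung	S25
CD26	ADA	experimental	lung;kidney	S26
CD26	CAV1	experimental	lung	S27
CD26	FAP	experimental	liver	S28
CD26	CXCR4	predicted	lung	S29
CD39	CD73	experimental	lung	S30
CD39	P2RX7	experimental	lung	S31
CD39	PANX1	predicted	brain	S32
CD73	ADORA2A	experimental	lung	S33
CD73	CAV1	experimental	lung	S34
CD73	P2RX7	predicted	lung	S35
PD-1	CEACAM1	experimental	lung	S36
BTLA	GRB2	experimental	lung	S37
TIM-3	PTPN6	predicted	lung	S38
LAG-3	PTPN6	experimental	lung	S39
ZAP70	CSK	experimental	lung	S40
LGALS9	CAV1	experimental	liver	S41
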