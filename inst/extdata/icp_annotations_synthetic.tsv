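protein	os_association	tumor_expression
PTPN11	positive	increased
GRB2	positive	increased
LCK	positive	decreased
ZAP70	positive	increased
FYN	none	unchanged
CSK	positive	increased
CD80	positive	increased
CAV1	negative	increased
LGALS9	positive	increased
CEACAM1	positive	increased
HLA-DRB1	positive	decreased
FGL1	negative	increased
PTPN6	positive	increased
TNFRSF14	positive	increased
PVR	negative	increased
PVRL2	none	increased
ADA	negative	unchanged
FAP	negative	increased
CXCR4	negative	increased
P2RX7	positive	increased
PANX1	none	unchanged
ADORA2A	positive	decreased
PD-1	positive	increased
PD-L1	positive	increased
TIM-3	positive	increased
LAG-3	positive	increased
BTLA	positive	increased
TIGIT	positive	increased
CD26	positive	increased
CD39	positive	increased
CD73	none	increased
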