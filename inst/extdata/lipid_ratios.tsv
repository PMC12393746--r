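label	numerator	denominator	annotation	provenance
Total PE Ether/PE	Total PE Ether	PE	ether-synthesis	printed
Total PC Ether/PC	Total PC Ether	PC	ether-synthesis	printed
PE(P)/PE	PE(P)	PE	ether-synthesis	printed
PE(O)/PE	PE(O)	PE	ether-synthesis	printed
PC(P)/PC	PC(P)	PC	ether-synthesis	printed
PC(O)/PC	PC(O)	PC	ether-synthesis	printed
TG(O)/TG	TG(O)	TG	ether-synthesis	printed
PE(O)/PE(P)	PE(O)	PE(P)	PEDS1	printed
PC(P)/PE(P)	PC(P)	PE(P)	headgroup	printed
LPE(P)/PE(P)	LPE(P)	PE(P)	iPLA2	printed
LPC(P)/PC(P)	LPC(P)	PC(P)	iPLA2	printed
LPE/PE	LPE	PE	iPLA2	printed
LPC/PC	LPC	PC	iPLA2	printed
PE/PC	PE	PC	PEMT	printed
PC(O)/PC(P)	PC(O)	PC(P)	PEDS1	printed
LPC(O)/PC(O)	LPC(O)	PC(O)	iPLA2	printed
PE(P-16:0/18:3)/PE(P-16:0/20:5)	PE(P-16:0/18:3)	PE(P-16:0/20:5)	omega-3	printed
PE(P-18:0/18:3)/PE(P-18:0/20:5)	PE(P-18:0/18:3)	PE(P-18:0/20:5)	omega-3	printed
PE(P-16:0/20:5)/PE(P-16:0/22:5) [n3]	PE(P-16:0/20:5)	PE(P-16:0/22:5) [n3]	omega-3	printed
PE(P-18:0/20:5)/PE(P-18:0/22:5) [n3]	PE(P-18:0/20:5)	PE(P-18:0/22:5) [n3]	omega-3	printed
PE(P-16:0/22:5) [n3]/PE(P-16:0/22:6)	PE(P-16:0/22:5) [n3]	PE(P-16:0/22:6)	omega-3	printed
PE(P-18:0/22:5) [n3]/PE(P-18:0/22:6)	PE(P-18:0/22:5) [n3]	PE(P-18:0/22:6)	omega-3	printed
PE(P-16:0/18:2)/PE(P-16:0/20:4)	PE(P-16:0/18:2)	PE(P-16:0/20:4)	omega-6	printed
PE(P-18:0/18:2)/PE(P-18:0/20:4)	PE(P-18:0/18:2)	PE(P-18:0/20:4)	omega-6	printed
PE(P-16:0/20:4)/PE(P-16:0/22:4)	PE(P-16:0/20:4)	PE(P-16:0/22:4)	omega-6	printed
PE(P-18:0/20:4)/PE(P-18:0/22:4)	PE(P-18:0/20:4)	PE(P-18:0/22:4)	omega-6	printed
PE(P-16:0/22:4)/PE(P-16:0/22:5) [n6]	PE(P-16:0/22:4)	PE(P-16:0/22:5) [n6]	omega-6	printed
PE(P-18:0/22:4)/PE(P-18:0/22:5) [n6]	PE(P-18:0/22:4)	PE(P-18:0/22:5) [n6]	omega-6	printed
PE(P-16:0/18:2)/PE(P-18:0/18:2)	PE(P-16:0/18:2)	PE(P-18:0/18:2)	sn1-composition	printed
PE(P-16:0/20:4)/PE(P-18:0/20:4)	PE(P-16:0/20:4)	PE(P-18:0/20:4)	sn1-composition	printed
PE(P-16:0/22:4)/PE(P-18:0/22:4)	PE(P-16:0/22:4)	PE(P-18:0/22:4)	sn1-composition	printed
PE(P-16:0/22:6)/PE(P-18:0/22:6)	PE(P-16:0/22:6)	PE(P-18:0/22:6)	sn1-composition	printed
LPE(16:0) [sn1]/LPE(18:0) [sn1]	LPE(16:0) [sn1]	LPE(18:0) [sn1]	lyso-chain	printed
LPE(16:0) [sn1]/LPE(18:1) [sn1]	LPE(16:0) [sn1]	LPE(18:1) [sn1]	lyso-chain	printed
LPC(16:0) [sn1]/LPC(18:0) [sn1]	LPC(16:0) [sn1]	LPC(18:0) [sn1]	lyso-chain	printed
LPC(16:0) [sn1]/LPC(18:1) [sn1]	LPC(16:0) [sn1]	LPC(18:1) [sn1]	lyso-chain	printed
LPE(16:0) [sn2]/LPE(18:0) [sn2]	LPE(16:0) [sn2]	LPE(18:0) [sn2]	lyso-chain	printed
LPE(16:0) [sn2]/LPE(18:2) [sn2]	LPE(16:0) [sn2]	LPE(18:2) [sn2]	lyso-chain	printed
LPC(16:0) [sn2]/LPC(18:0) [sn2]	LPC(16:0) [sn2]	LPC(18:0) [sn2]	lyso-chain	printed
LPC(16:0) [sn2]/LPC(18:2) [sn2]	LPC(16:0) [sn2]	LPC(18:2) [sn2]	lyso-chain	printed
PE(18:0_22:4)/PE(18:0_22:5)	PE(18:0_22:4)	PE(18:0_22:5)	PUFA	printed
PE(18:0_22:5)/PE(18:0_22:6)	PE(18:0_22:5)	PE(18:0_22:6)	PUFA	printed
PC(18:0_22:4)/PC(18:0_22:5)	PC(18:0_22:4)	PC(18:0_22:5)	PUFA	printed
LPC(22:5) [sn2]/LPC(22:6) [sn2]	LPC(22:5) [sn2]	LPC(22:6) [sn2]	PUFA	printed
LPC(20:4) [sn2]/LPC(22:4) [sn2]	LPC(20:4) [sn2]	LPC(22:4) [sn2]	omega-6	printed
PE(16:0_18:2)/PE(16:0_20:4)	PE(16:0_18:2)	PE(16:0_20:4)	omega-6	printed
PE(P-16:0/18:3)/PE(P-18:1/18:3)	PE(P-16:0/18:3)	PE(P-18:1/18:3)	sn1-composition	printed
PC(P-16:0/20:4)/PE(P-16:0/20:4)	PC(P-16:0/20:4)	PE(P-16:0/20:4)	headgroup	printed
LPE(P)/LPE	LPE(P)	LPE	lyso-ether	reconstructed
LPC(P)/LPC	LPC(P)	LPC	lyso-ether	reconstructed
LPC(O)/LPC	LPC(O)	LPC	lyso-ether	reconstructed
PE(O)/PC(O)	PE(O)	PC(O)	headgroup	reconstructed
PE(O-16:0/20:4)/PE(P-16:0/20:4)	PE(O-16:0/20:4)	PE(P-16:0/20:4)	PEDS1	reconstructed
PE(O-18:0/20:4)/PE(P-18:0/20:4)	PE(O-18:0/20:4)	PE(P-18:0/20:4)	PEDS1	reconstructed
CE/COH	CE	COH	esterification	reconstructed
Cer/dhCer	Cer	dhCer	DES1	reconstructed
SM/Cer	SM	Cer	SMS	reconstructed
HexCer/Cer	HexCer	Cer	glycosylation	reconstructed
Hex2Cer/HexCer	Hex2Cer	HexCer	glycosylation	reconstructed
Hex3Cer/Hex2Cer	Hex3Cer	Hex2Cer	glycosylation	reconstructed
GM3/Hex2Cer	GM3	Hex2Cer	glycosylation	reconstructed
dhSM/dhCer	dhSM	dhCer	SMS	reconstructed
CerP/Cer	CerP	Cer	CERK	reconstructed
LPI/PI	LPI	PI	phospholipase	reconstructed
LPS/PS	LPS	PS	phospholipase	reconstructed
LPG/PG	LPG	PG	phospholipase	reconstructed
DG/PA	DG	PA	lipin	reconstructed
TG/DG	TG	DG	DGAT	reconstructed
DG/MG	DG	MG	MGAT	reconstructed
PS/PE	PS	PE	PSS	reconstructed
PI/PA	PI	PA	CDP-DAG	reconstructed
FFA(16:1)/FFA(16:0)	FFA(16:1)	FFA(16:0)	DNL	reconstructed
FFA(18:1)/FFA(18:0)	FFA(18:1)	FFA(18:0)	SCD1	reconstructed
FFA(18:0)/FFA(16:0)	FFA(18:0)	FFA(16:0)	DNL	reconstructed
CE(16:1)/CE(16:0)	CE(16:1)	CE(16:0)	DNL	reconstructed
CE(20:4)/CE(18:2)	CE(20:4)	CE(18:2)	omega-6	reconstructed
CE(20:5)/CE(18:3)	CE(20:5)	CE(18:3)	omega-3	reconstructed
FFA(20:4)/FFA(18:2)	FFA(20:4)	FFA(18:2)	omega-6	reconstructed
FFA(20:5)/FFA(18:3)	FFA(20:5)	FFA(18:3)	omega-3	reconstructed
FFA(22:6)/FFA(20:5)	FFA(22:6)	FFA(20:5)	omega-3	reconstructed
PC(18:0_22:5)/PC(18:0_22:6)	PC(18:0_22:5)	PC(18:0_22:6)	PUFA	reconstructed
PE(16:0_18:2)/PE(18:0_18:2)	PE(16:0_18:2)	PE(18:0_18:2)	sn1-composition	reconstructed
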