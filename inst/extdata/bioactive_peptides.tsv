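sequence	parent	bioactivities	enzymes
VVPP	beta_casein:f(83-86)	ACE inhibition	PRA205
VKEAMAPK	beta_casein:f(98-105)	Antioxidant;Antimicrobial	2006
EAMAPK	beta_casein:f(100-105)	Antimicrobial	2006
SQSKVLPVPQ	beta_casein:f(166-175)	ACE inhibition	PRA205;2006
KVLPVPQ	beta_casein:f(169-175)	ACE inhibition	2006
VLPVPQKAVPYPQR	beta_casein:f(170-183)	Antimicrobial	PRA205;2006
VLPVPQK	beta_casein:f(170-176)	ACE inhibition;Antioxidant;Antimicrobial	2006
LPVPQ	beta_casein:f(171-175)	DPP-IV inhibition	PRA205;2006
PYPQ	beta_casein:f(179-182)	Antioxidant	PRA205;2006
RDMPIQAF	beta_casein:f(183-190)	ACE inhibition	PRA205;2006
LLY	beta_casein:f(191-193)	Immunomodulation	PRA205;2006
LLYQEPVLGPVRGPFPIIV	beta_casein:f(191-209)	ACE inhibition	PRA205;2006
LYQEPVLGPVRGPFPIIV	beta_casein:f(192-209)	Immunomodulation	PRA205;2006
YQEPVLGPVR	beta_casein:f(193-202)	ACE inhibition;Immunomodulation	PRA205;2006
YQEPVLGPVRGPFPI	beta_casein:f(193-207)	Antimicrobial	PRA205;2006
YQEPVLGPVRGPFPIIV	beta_casein:f(193-209)	ACE inhibition;Immunomodulation;Antimicrobial	PRA205;2006
QEPVLGPVRGPFPIIV	beta_casein:f(194-209)	ACE inhibition	PRA205;2006
EPVLGPVRGPFP	beta_casein:f(195-206)	ACE inhibition	PRA205;2006
RPKHPIK	as1_casein:f(1-7)	Antimicrobial	2006
RPKHPIKHQ	as1_casein:f(1-9)	ACE inhibition	2006
RPKHPIKHQGLPQEVLNENLLRF	as1_casein:f(1-23)	Immunomodulation;Antimicrobial	PRA205;2006
RPKHPIKHQGLPQEVLNENLLRFF	as1_casein:f(1-24)	Antimicrobial	PRA205;2006
RPKHPIKHQGLPQEVLNENLLRFFVAPFPEVFGKEK	as1_casein:f(1-36)	Antimicrobial	2006
VLNENLLR	as1_casein:f(15-22)	Antimicrobial	PRA205;2006
YLGYLEQLLR	as1_casein:f(91-100)	Anxiolytic	PRA205
LGY	as1_casein:f(92-94)	ACE inhibition;Antioxidant	PRA205;2006
LGYLEQLLRL	as1_casein:f(92-101)	Antimicrobial	PRA205;2006
YLEQLLR	as1_casein:f(94-100)	Antimicrobial	PRA205;2006
PEL	as1_casein:f(147-149)	Antioxidant	PRA205;2006
GTQYTDAPSFSDIPNPIGSENSEKTTMPLW	as1_casein:f(170-199)	ACE inhibition;Antioxidant	PRA205;2006
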