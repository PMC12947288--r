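catalyst	ligand	precatalyst_class
SPhos Pd(allyl)OTf	SPhos	allyl-triflate
SPhos Pd(crotyl)Cl	SPhos	allyl-triflate
SPhos Pd G3	SPhos	G3
XPhos Pd G3	XPhos	G3
tBuXPhos Pd G3	tBuXPhos	G3
tBuXPhos Pd(allyl)OTf	tBuXPhos	allyl-triflate
Pd-PEPPSI-IPent Cl o-picoline	IPent Cl	PEPPSI
Pd-PEPPSI-IPent Cl 3-chloropyridine	IPent Cl	PEPPSI
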