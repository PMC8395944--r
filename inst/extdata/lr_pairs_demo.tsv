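ligand	receptor	pathway
Ccl2	Ccr2	CCL
Ccl12	Ccr2	CCL
Ccl7	Ccr2	CCL
Ccl7	Ccr1	CCL
Ccl8	Ccr2	CCL
Ccl8	Ccr5	CCL
Ccl3	Ccr1	CCL
Ccl3	Ccr5	CCL
Ccl4	Ccr5	CCL
Ccl5	Ccr1	CCL
Ccl5	Ccr3	CCL
Ccl5	Ccr5	CCL
Ccl17	Ccr4	CCL
Ccl22	Ccr4	CCL
Ccl19	Ccr7	CCL
Ccl21a	Ccr7	CCL
Cx3cl1	Cx3cr1	CX3C
Cxcl1	Cxcr2	CXCL
Cxcl2	Cxcr2	CXCL
Cxcl5	Cxcr2	CXCL
Cxcl9	Cxcr3	CXCL
Cxcl10	Cxcr3	CXCL
Cxcl11	Cxcr3	CXCL
Cxcl12	Cxcr4	CXCL
Cxcl13	Cxcr5	CXCL
Cd74	Cxcr4	MIF
Cd74	Cxcr2	MIF
Ifng	Ifngr1	IFN
Ifng	Ifngr2	IFN
Il1b	Il1r1	IL
Il2	Il2ra	IL
Il2	Il2rb	IL
Il6	Il6ra	IL
Il10	Il10ra	IL
Il12a	Il12rb1	IL
Il15	Il15ra	IL
Il18	Il18r1	IL
Tnf	Tnfrsf1a	TNF
Tnf	Tnfrsf1b	TNF
Tgfb1	Tgfbr1	TGF
Tgfb1	Tgfbr2	TGF
Csf1	Csf1r	CSF
Csf2	Csf2ra	CSF
Csf2	Csf2rb	CSF
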