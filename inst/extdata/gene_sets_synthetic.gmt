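TGF_SIGNALING	synthetic illustrative stand-in for a TGF-beta receptor signaling membership list; replace with a curated set	TGFB1	TGFBR1	TGFBR2	SMAD2	SMAD3	SMAD4	SMAD7	SERPINE1	FN1	SPP1	THBS1	LTBP1
FIBROBLAST_ACTIVATION	synthetic illustrative stand-in for an activated-fibroblast signature; replace with a curated set	ACTA2	COL1A1	COL1A2	COL3A1	FN1	POSTN	CTHRC1	TNC	SPARC	FAP	LOX	TIMP1
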