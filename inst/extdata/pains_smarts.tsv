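# Curated pan-assay interference (PAINS-style) substructure motifs.
# Classic frequent-hitter chemotypes (quinones, catechols, rhodanines,
# hydrazones, azo dyes, alkylidene barbiturates, aromatic nitro groups),
# written as OpenBabel-compatible SMARTS after the motif classes described
# by Baell & Holloway (J Med Chem 2010) and common web-filter sets.
name	smarts	source
para_quinone	O=C1C=CC(=O)C=C1	quinone frequent hitter
ortho_quinone	O=C1C(=O)C=CC=C1	quinone frequent hitter
catechol	Oc1ccccc1O	redox-active catechol
rhodanine	S=C1NC(=O)CS1	rhodanine core
ene_rhodanine	C=C1SC(=S)NC1=O	alkylidene rhodanine
aryl_hydrazone	c1ccccc1C=NN	hydrazone frequent hitter
azo_aryl	cN=Nc	azo dye
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=C	barbiturate Michael acceptor
nitro_aromatic	c[N+](=O)[O-]	aromatic nitro
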