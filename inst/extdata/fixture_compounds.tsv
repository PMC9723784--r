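# Worked-example compound catalog: plastic-derived (PDCC) and
# lignin-derived (LDCC) chemical compounds with standard-structure SMILES.
id	name	smiles	partition	xref
monomethyl_phthalate	monomethyl phthalate	COC(=O)c1ccccc1C(=O)O	PDCC	
dihydroxyphthalate	3,4-dihydroxyphthalate	OC(=O)c1c(C(=O)O)c(O)c(O)cc1	PDCC	
terephthalate	terephthalic acid	OC(=O)c1ccc(cc1)C(=O)O	PDCC	
hydroxybutyrate	3-hydroxybutyric acid	CC(O)CC(=O)O	PDCC	
hydroxyvalerate	3-hydroxyvalerate	CCC(O)CC(=O)O	PDCC	
vanillate	vanillate	COc1cc(ccc1O)C(=O)O	LDCC	
muconate	cis,cis-muconic acid	OC(=O)C=CC=CC(=O)O	LDCC	
benzoate	benzoic acid	OC(=O)c1ccccc1	LDCC	
catechol	catechol	Oc1ccccc1O	LDCC	
protocatechuate	protocatechuate	OC(=O)c1ccc(O)c(O)c1	LDCC	
hydroxybenzoate	4-hydroxybenzoate	OC(=O)c1ccc(O)cc1	LDCC	
salicylate	salicylate	OC(=O)c1ccccc1O	LDCC	
oxoadipate	3-oxoadipate	OC(=O)CCC(=O)CC(=O)O	LDCC	
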