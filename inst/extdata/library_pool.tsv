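id	smiles	pool
POOL_IN_01	O=C(Nc1ccc(Br)cc1)c1ccc2ccccc2c1	in
POOL_IN_02	O=S(=O)(N1CCCCC1)c1ccc(F)cc1OCc1ccccc1	in
POOL_IN_03	Clc1ccc(Cn2ccnc2C(=O)N3CCOCC3)cc1	in
POOL_IN_04	O=C(Nc1nc2ccc(Cl)cc2s1)c1ccc(OC)cc1	in
POOL_IN_05	O=C(c1ccc(Br)cc1)N1CCc2ccccc2C1	in
POOL_IN_06	O=S(=O)(Nc1ccccn1)c1ccc(NC(=O)C)cc1Cl	in
POOL_IN_07	O=C(COc1ccc(Cl)cc1)Nc1ccccc1C(=O)NC	in
POOL_IN_08	Cn1c(=O)c2c(ncn2CC(=O)Nc2ccccc2)n(C)c1=O	in
POOL_IN_09	O=C(Nc1ccc2c(c1)CCO2)c1cc2ccccc2nc1Cl	in
POOL_IN_10	COc1ccc(-c2nc3sccn3c2-c2ccccn2)cc1	in
POOL_IN_11	Clc1cccc(N2CCN(Cc3ccsc3)CC2)c1Cl	in
POOL_IN_12	O=C(OC1CCCCC1)c1cccc(NC(=O)c2ccco2)c1	in
POOL_IN_13	O=C1N(CCN2CCOCC2)C(=O)c2cc(Br)ccc21	in
POOL_IN_14	Cc1onc(-c2ccccc2Cl)c1C(=O)Nc1ccc(C)cc1	in
POOL_IN_15	O=C(Cc1cccs1)NCCc1c[nH]c2ccc(OC)cc12	in
POOL_IN_16	O=[N+]([O-])c1ccc(NC(=S)Nc2ccc(OC)cc2OC)cc1	in
POOL_IN_17	COC(=O)c1ccc(NC(=O)c2cccc3cccnc23)cc1	in
POOL_IN_18	Cc1nn(-c2ccccc2)c(C)c1C(=O)OCC(=O)c1ccccc1	in
POOL_IN_19	O=C(Nc1ccccc1N1CCCCC1)c1ccc(F)c(F)c1	in
POOL_IN_20	CC(=O)Nc1ccc(S(=O)(=O)Nc2ccccc2OC)cc1	in
POOL_OUT_01	CC(=O)Oc1ccccc1C(=O)O	out
POOL_OUT_02	Cn1cnc2c1c(=O)n(C)c(=O)n2C	out
POOL_OUT_03	CC(C)Cc1ccc(C(C)C(=O)O)cc1	out
POOL_OUT_04	COc1ccc2cc(C(C)C(=O)O)ccc2c1	out
POOL_OUT_05	c1ccc2ccccc2c1	out
POOL_OUT_06	O=C(Nc1ccc(Br)cc1)c1ccc(C(=O)Nc2ccc(Br)cc2)cc1	out
POOL_VIOL_01	OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O	viol
POOL_VIOL_02	OCC1OC(OC2OC(CO)C(O)C(O)C2O)C(O)C(O)C1O	viol
POOL_VIOL_03	OCC(O)C(O)C(O)C(O)COC1OC(CO)C(O)C(O)C1O	viol
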