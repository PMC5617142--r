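chemical_id,TEC,MEC,PEC,source
"1,4-Dichlorobenzene",31,60.5,90,WIDNR sediment quality guidelines
2-Methylnaphthalene,20.2,111,201,WIDNR sediment quality guidelines
Anthracene,57.2,451,845,WIDNR sediment quality guidelines
Benzo[a]pyrene,150,800,1450,WIDNR sediment quality guidelines
Fluoranthene,423,1327,2230,WIDNR sediment quality guidelines
Naphthalene,176,369,561,WIDNR sediment quality guidelines
Phenanthrene,204,687,1170,WIDNR sediment quality guidelines
Phenol,4200,8100,12000,WIDNR sediment quality guidelines
Pyrene,195,858,1520,WIDNR sediment quality guidelines
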