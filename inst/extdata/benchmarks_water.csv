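chemical_id,value,kind,source
4-Nonylphenol,1.00,chronic,aggregated US/Canada benchmark compilation
Anthracene,0.01,chronic,aggregated US/Canada benchmark compilation
Benzo[a]pyrene,0.01,chronic,aggregated US/Canada benchmark compilation
Bis(2-ethylhexyl) phthalate,0.30,chronic,aggregated US/Canada benchmark compilation
Dichlorvos,0.01,chronic,aggregated US/Canada benchmark compilation
Fluoranthene,0.04,chronic,aggregated US/Canada benchmark compilation
Pyrene,0.03,chronic,aggregated US/Canada benchmark compilation
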