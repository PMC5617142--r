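chemical_id,value,kind,source
PAH-01,0.2,chronic,synthetic benchmark for the simulated panel
PAH-02,0.2,chronic,synthetic benchmark for the simulated panel
PAH-03,0.3,chronic,synthetic benchmark for the simulated panel
PEST-01,1.5,chronic,synthetic benchmark for the simulated panel
PEST-02,1.5,chronic,synthetic benchmark for the simulated panel
PEST-03,2.0,acute,synthetic benchmark for the simulated panel (acute only)
ALKP-01,1.0,chronic,synthetic benchmark for the simulated panel
PHARM-01,10,chronic,synthetic benchmark for the simulated panel
FLAME-01,5,chronic,synthetic benchmark for the simulated panel
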