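chemical_id,TEC,MEC,PEC,source
PAH-01,0.3,1.5,3,synthetic guideline for the simulated panel
PAH-02,0.3,1.5,3,synthetic guideline for the simulated panel
PAH-03,0.4,2,4,synthetic guideline for the simulated panel
FRAG-01,0.5,2.5,5,synthetic guideline for the simulated panel
ALKP-01,1,5,10,synthetic guideline for the simulated panel
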