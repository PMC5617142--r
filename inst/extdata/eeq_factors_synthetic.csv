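chemical_id,eeq_factor,source
HORM-01,1.0,synthetic example factor (17beta-estradiol-like reference potency)
HORM-02,0.3,synthetic example factor (estrone-like potency)
ALKP-01,3e-05,synthetic example factor (nonylphenol-like potency)
PLAS-01,1e-05,synthetic example factor (bisphenol-A-like potency)
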